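# normalization, filtering, the NB Wald test, profiles and clustering

test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(2, 8, 2, 8), 2, 2)
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- matrix(c(2, 8, 4, 16), 2, 2)
  # geometric means (2.828, 11.314); ratios per sample all 0.7071 / 1.4142
  expect_equal(unname(size_factors(m2)), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-12)

  set.seed(3)
  m3 <- matrix(rnbinom(300, mu = 100, size = 10) + 1, 50, 6)
  f3 <- size_factors(m3)
  scaled <- m3
  scaled[, 2] <- scaled[, 2] * 3
  f3s <- size_factors(scaled)
  # size factors are defined up to a common constant (the per-gene
  # reference includes the scaled sample), so equivariance holds on ratios
  expect_equal(unname(f3s[2] / f3s[1]), unname(3 * f3[2] / f3[1]))
  expect_equal(unname(f3s[3:6] / f3s[1]), unname(f3[3:6] / f3[1]))
  # gene-order invariance
  expect_equal(unname(size_factors(m3[sample(50), ])), unname(f3))

  zero <- matrix(c(0, 5, 3, 0), 2, 2)
  expect_error(size_factors(zero), "normalization impossible")
})

test_that("size factors agree with the reference normalization routine", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  m <- matrix(rnbinom(55 * 8, mu = 200, size = 5) + 1, 55, 8)
  # odd number of all-nonzero genes so the median is a single order statistic
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("low-count filter applies the per-species reading of the rule", {
  counts <- rbind(allzero = rep(0L, 6),
                  onehit = c(10L, 0L, 0L, 0L, 0L, 0L),
                  low = c(9L, 9L, 9L, 9L, 9L, 9L),
                  high = rep(50L, 6))
  colnames(counts) <- sprintf("s%d", 1:6)
  meta <- data.frame(sample_id = colnames(counts),
                     species = rep(c("A", "B"), each = 3),
                     stage = 1, replicate = rep(1:3, 2))
  kept <- low_count_filter(counts, meta)
  expect_setequal(kept, c("onehit", "high"))  # 10 is not < 10
  # "either" mode also removes genes low in just one species
  kept2 <- low_count_filter(counts, meta, mode = "either")
  expect_setequal(kept2, "high")
})

test_that("identical groups give zero fold change and moderate p-values", {
  set.seed(21)
  base <- matrix(rnbinom(40 * 3, mu = 100, size = 20), 40, 3)
  counts <- cbind(base, base)
  colnames(counts) <- sprintf("s%d", 1:6)
  rownames(counts) <- sprintf("g%d", 1:40)
  meta <- data.frame(sample_id = colnames(counts),
                     species = rep(c("A", "B"), each = 3),
                     stage = 1, replicate = rep(1:3, 2))
  de <- de_contrast(counts, setNames(rep(1, 6), colnames(counts)), meta,
                    list(group1 = paste0("s", 1:3),
                         group2 = paste0("s", 4:6)))
  expect_equal(de$log2fc, rep(0, 40))
  expect_equal(de$pvalue, rep(1, 40))
})

test_that("planted four-fold genes are recovered at high rate", {
  set.seed(33)
  n <- 400
  mu <- rep(500, n)
  planted <- 1:80
  mu2 <- mu
  mu2[planted] <- mu2[planted] * 4
  counts <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 1 / 0.05), n, 3),
                  matrix(rnbinom(n * 3, mu = mu2, size = 1 / 0.05), n, 3))
  colnames(counts) <- sprintf("s%d", 1:6)
  rownames(counts) <- sprintf("g%d", 1:n)
  meta <- data.frame(sample_id = colnames(counts),
                     species = rep(c("A", "B"), each = 3),
                     stage = 1, replicate = rep(1:3, 2))
  de <- de_contrast(counts, setNames(rep(1, 6), colnames(counts)), meta,
                    list(group1 = paste0("s", 1:3),
                         group2 = paste0("s", 4:6)))
  hit <- abs(de$log2fc[planted]) >= 1.5 & de$padj[planted] < 0.05
  expect_gte(mean(hit), 0.9)
})

test_that("BH adjustment is monotone in the raw p-values", {
  set.seed(2)
  fx <- make_counts_fixture(seed = 12, n_genes = 150)
  de <- de_contrast(fx$counts, fx$factors, fx$meta,
                    species_stage_contrasts(fx$meta)[[1]])
  ord <- order(de$pvalue)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))
  expect_true(all(de$padj >= de$pvalue - 1e-12))
})

test_that("DEG calls apply both thresholds with an inclusive fold bound", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(0.585, 2, -0.6, 0.1),
                    padj = c(0.01, 0.06, 0.04, 0.001))
  got <- call_degs(rec)
  expect_equal(got$records$is_deg, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(got$deg_genes, c("a", "c"))

  set.seed(14)
  r2 <- data.frame(gene_id = sprintf("g%d", 1:500),
                   log2fc = rnorm(500, sd = 1),
                   padj = runif(500))
  got2 <- call_degs(r2)
  expect_equal(got2$records$is_deg,
               abs(r2$log2fc) >= 0.585 & r2$padj < 0.05)
})

test_that("stage profiles are Z-scored per gene and flag constant genes", {
  counts <- rbind(g1 = c(10L, 10L, 20L, 20L, 30L, 30L, 40L, 40L),
                  gconst = rep(7L, 8))
  colnames(counts) <- sprintf("s%d", 1:8)
  meta <- data.frame(sample_id = colnames(counts),
                     species = rep(c("A", "B"), each = 4),
                     stage = rep(c(1, 2), 2, each = 2),
                     replicate = rep(1:2, 4))
  prof <- stage_profiles(counts, setNames(rep(1, 8), colnames(counts)), meta)
  # g1 cell means are (10, 20, 30, 40): mean 25, sd = sqrt(500/3)
  expected <- (c(10, 20, 30, 40) - 25) / sqrt(500 / 3)
  expect_equal(unname(prof$z["g1", c("A_s1", "A_s2", "B_s1", "B_s2")]),
               expected)
  expect_true(prof$excluded["gconst"])
  expect_equal(unname(prof$z["gconst", ]), rep(0, 4))

  fx <- make_counts_fixture(seed = 31)
  pr <- stage_profiles(fx$counts, fx$factors, fx$meta)
  ok <- !pr$excluded
  expect_true(all(abs(rowMeans(pr$z[ok, ])) < 1e-9))
  expect_true(all(abs(apply(pr$z[ok, ], 1, sd) - 1) < 1e-9))
})

test_that("complete-linkage clustering separates planted archetypes", {
  set.seed(8)
  z <- rbind(matrix(rnorm(10 * 6, mean = 3), 10, 6),
             matrix(rnorm(10 * 6, mean = -3), 10, 6))
  rownames(z) <- sprintf("g%d", 1:20)
  cl <- cluster_profiles(z, k = 2)
  truth <- rep(1:2, each = 10)
  expect_equal(length(unique(cl$assignment[1:10])), 1)
  expect_equal(length(unique(cl$assignment[11:20])), 1)
  expect_false(cl$assignment[1] == cl$assignment[20])

  # duplicated profiles always co-cluster
  z2 <- rbind(z, dup = z[1, ])
  cl2 <- cluster_profiles(z2, k = 2)
  expect_equal(unname(cl2$assignment["dup"]),
               unname(cl2$assignment["g1"]))

  expect_error(cluster_profiles(z[1:3, ], k = 7), "at least k")
})

test_that("clustering is invariant to row permutation up to relabeling", {
  skip_if_not_installed("mclust")
  set.seed(26)
  fx <- make_counts_fixture(seed = 61, n_genes = 140)
  prof <- stage_profiles(fx$counts, fx$factors, fx$meta)
  cl <- cluster_profiles(prof, k = 7)
  z <- prof$z[!prof$excluded, ]
  perm <- sample(nrow(z))
  clp <- cluster_profiles(z[perm, ], k = 7)
  ari <- mclust::adjustedRandIndex(cl$assignment[rownames(z)[perm]],
                                   clp$assignment)
  expect_equal(ari, 1)
})
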
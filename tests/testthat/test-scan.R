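# xpEHH scan machinery: frequencies, MAF filter, EHHS, iES, standardization

toy_panel <- function() {
  # 4 haplotypes over positions (100, 200, 300); focal site 2 is monomorphic
  haplotype_matrix(rbind(c(0L, 1L, 0L),
                         c(0L, 1L, 0L),
                         c(1L, 1L, 1L),
                         c(0L, 1L, 1L)),
                   positions = c(100, 200, 300))
}

test_that("site frequencies match a direct per-column recount", {
  h <- haplotype_matrix(matrix(c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L), 4, 2),
                        positions = c(10, 20))
  f <- site_frequencies(h)
  expect_equal(f$freq, c(0, 0.5))
  expect_equal(f$maf, c(0, 0.5))

  set.seed(101)
  hr <- random_panel(100, 50)
  fr <- site_frequencies(hr)
  expect_equal(fr$freq, unname(apply(hr$alleles, 2, function(x)
    sum(x) / length(x))))
  expect_equal(fr$maf, pmin(fr$freq, 1 - fr$freq))

  expect_error(haplotype_matrix(matrix(integer(0), 0, 0), numeric(0)),
               "non-empty")
})

test_that("pooled MAF filter is strict at the threshold", {
  # pooled sample of 120 haplotypes: 6/120 = 0.05 exactly -> excluded,
  # 7/120 > 0.05 -> retained, monomorphic -> excluded
  mk <- function(counts) {
    al <- sapply(counts, function(k) rep(c(1L, 0L), c(k, 60 - k)))
    haplotype_matrix(al, positions = seq(100, by = 100,
                                         length.out = length(counts)))
  }
  A <- mk(c(3, 4, 0))
  B <- mk(c(3, 3, 0))
  expect_equal(joint_maf_filter(A, B), 2L)

  allmono <- mk(c(0, 0, 0))
  expect_length(joint_maf_filter(allmono, allmono), 0)

  set.seed(7)
  Ar <- random_panel(30, 40)
  Br <- haplotype_matrix(matrix(rbinom(20 * 40, 1, 0.5), 20, 40),
                         Ar$positions)
  got <- joint_maf_filter(Ar, Br)
  pooled <- (colSums(Ar$alleles) + colSums(Br$alleles)) / 50
  expect_equal(got, which(pmin(pooled, 1 - pooled) > 0.05))

  Bshift <- haplotype_matrix(Br$alleles, Br$positions + 5)
  expect_error(joint_maf_filter(Ar, Bshift), "identical")
})

test_that("EHHS matches hand enumeration on the 4-haplotype toy", {
  p <- ehhs_profile(toy_panel(), 2)
  # right side: groups over [200,300] are {h1,h2} and {h3,h4} -> 2/6
  expect_equal(p$right_values, c(1, 1 / 3))
  # left side: groups over [100,200] are {h1,h2,h4} and {h3} -> 3/6
  expect_equal(p$left_values, c(1, 1 / 2))
  expect_equal(p$right_positions, c(200, 300))
  expect_true(p$censored_left && p$censored_right)
})

test_that("EHHS equals the homozygous-pair enumeration oracle", {
  set.seed(31)
  for (rep in 1:12) {
    h <- random_panel(sample(4:30, 1), sample(10:80, 1))
    focal <- sample(ncol(h$alleles), 1)
    p <- ehhs_profile(h, focal)
    expect_equal(p$right_values,
                 oracle_ehhs_side(h$alleles, focal, +1), tolerance = 1e-12)
    expect_equal(p$left_values,
                 oracle_ehhs_side(h$alleles, focal, -1), tolerance = 1e-12)
    expect_true(all(diff(p$right_values) <= 1e-12))
    expect_true(all(diff(p$left_values) <= 1e-12))
    expect_equal(p$right_values[1], 1)
  }
})

test_that("identical haplotypes keep EHHS at 1 to every reachable site", {
  al <- matrix(rep(c(0L, 1L, 0L, 1L, 1L), each = 6), 6, 5)
  h <- haplotype_matrix(al, positions = c(10, 500, 900, 1500, 2000))
  p <- ehhs_profile(h, 3)
  expect_equal(p$left_values, rep(1, 3))
  expect_equal(p$right_values, rep(1, 3))
  ies <- integrate_ies(p)
  expect_equal(ies$ies, 2000 - 10)  # full inter-edge span
  expect_true(ies$censored)

  expect_error(ehhs_profile(haplotype_matrix(al[1:3, ], h$positions), 1),
               "4 haplotypes")
})

test_that("a gap beyond max_gap_bp censors the profile side", {
  set.seed(12)
  h <- random_panel(10, 20, span = 4000)
  h$positions[15:20] <- h$positions[15:20] + 5e5
  p <- ehhs_profile(h, 10, scan_config(max_gap_bp = 2e5))
  expect_lt(length(p$right_values), 12)  # walk stops at the gap
})

test_that("trapezoidal iES matches hand integration", {
  p <- ehhs_profile(toy_panel(), 2)
  # right: (1 + 1/3)/2 * 100; left: (1 + 1/2)/2 * 100
  expect_equal(integrate_ies(p)$ies, 200 / 3 + 75, tolerance = 1e-12)

  # truncation: the first sub-threshold site contributes its trapezoid and
  # stops the side
  fake <- structure(list(focal_index = 1L,
                         left_values = 1, left_positions = 1000,
                         right_values = c(1, 0.5, 0.01, 0.8),
                         right_positions = c(1000, 1100, 1200, 1300),
                         censored_left = TRUE, censored_right = FALSE),
                    class = "ehhs_profile")
  expect_equal(integrate_ies(fake)$ies,
               (1 + 0.5) / 2 * 100 + (0.5 + 0.01) / 2 * 100)

  single <- structure(list(focal_index = 1L, left_values = 1,
                           left_positions = 50, right_values = 1,
                           right_positions = 50, censored_left = TRUE,
                           censored_right = TRUE),
                      class = "ehhs_profile")
  expect_equal(integrate_ies(single)$ies, 0)
})

test_that("standardization and two-sided -log10 p behave as expected", {
  std <- standardize_and_logp(c(-2, -1, 0, 1, 2))
  expect_equal(std$z[3], 0)
  expect_equal(std$logp[3], 0)

  # |z| = 3.2905 is the two-sided 0.001 point of the standard normal
  raw <- c(rnorm(50))
  z <- (raw - mean(raw)) / sd(raw)
  expect_equal(-log10(2 * pnorm(-3.2905)), 3, tolerance = 1e-4)

  neg <- standardize_and_logp(-c(-2, -1, 0, 1, 2))
  expect_equal(neg$z, -std$z)
  expect_equal(neg$logp, std$logp)

  expect_error(standardize_and_logp(rep(1, 5)), "degenerate")
  expect_error(standardize_and_logp(c(1, NA, 2)), "finite")
  expect_error(standardize_and_logp(c(1, Inf, 2)), "finite")
})

test_that("population swap negates raw and z and preserves logp", {
  sim <- simulate_haplotypes(hap_sim_config(
    n_haplotypes_per_pop = 30, chrom_length = 1e5, n_sites = 800,
    pop_size = 200, n_generations = 40, recombination_rate = 1e-5,
    seed = 17))
  ab <- xpehh_scan(sim$pop_a, sim$pop_b)
  ba <- xpehh_scan(sim$pop_b, sim$pop_a)
  expect_gt(nrow(ab), 100)
  expect_equal(ba$xpehh_raw, -ab$xpehh_raw)
  expect_equal(ba$z, -ab$z)
  expect_equal(ba$logp, ab$logp)
  expect_equal(ba$pos, ab$pos)
  expect_equal(ab$maf_A, ba$maf_B)
})

test_that("scan rejects degenerate input and warns on empty results", {
  # keeping censored sites, identical panels give identical integrals and
  # a zero-variance raw vector
  h <- toy_panel()
  expect_error(xpehh_scan(h, h, scan_config(drop_censored = FALSE)),
               "degenerate")

  mono <- haplotype_matrix(matrix(0L, 6, 3), c(10, 20, 30))
  expect_warning(res <- xpehh_scan(mono, mono), "no sites")
  expect_equal(nrow(res), 0)
})

test_that("scan output is sorted with finite statistics", {
  sim <- simulate_haplotypes(hap_sim_config(
    n_haplotypes_per_pop = 24, chrom_length = 8e4, n_sites = 600,
    pop_size = 150, n_generations = 40, recombination_rate = 1e-5,
    seed = 23))
  scan <- xpehh_scan(sim$pop_a, sim$pop_b)
  expect_false(is.unsorted(scan$pos, strictly = TRUE))
  expect_true(all(is.finite(scan$z)))
  expect_true(all(scan$logp >= 0))
  expect_true(all(scan$iES_A > 0 & scan$iES_B > 0))
  expect_equal(scan$xpehh_raw, log(scan$iES_A / scan$iES_B))
  expect_false(any(scan$censored))
  # standardization is exact over the retained set
  expect_equal(mean(scan$z), 0, tolerance = 1e-12)
  expect_equal(sd(scan$z), 1, tolerance = 1e-12)
})
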
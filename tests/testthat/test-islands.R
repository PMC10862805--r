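# significance filtering, island merging and closest-gene linking

test_that("significance threshold is inclusive at logp = 3", {
  rec <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                    logp = c(2.999, 3, 5))
  sig <- significant_sites(rec)
  expect_equal(sig$pos, c(200, 300))

  none <- significant_sites(data.frame(chrom = "chr1", pos = 1:5,
                                       logp = rep(0, 5)))
  expect_equal(nrow(none), 0)

  set.seed(4)
  r <- data.frame(chrom = "chr1", pos = seq_len(200) * 10,
                  logp = runif(200, 0, 6))
  expect_equal(significant_sites(r, 2.5)$pos, r$pos[r$logp >= 2.5])
})

test_that("island merging reproduces the hand-worked example", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 40000, 120000),
                      logp = c(3, 4, 5))
  isl <- merge_islands(sites, 50000)
  expect_equal(nrow(isl), 2)
  expect_equal(isl$start, c(100, 120000))
  expect_equal(isl$end, c(40000, 120000))
  expect_equal(isl$n_sig_snps, c(2L, 1L))
  expect_equal(isl$max_logp, c(4, 5))
  expect_equal(isl$mean_logp, c(3.5, 5))

  single <- merge_islands(data.frame(chrom = "chr1", pos = 5000), 50000)
  expect_equal(single$start, 5000)
  expect_equal(single$end, 5000)
  expect_equal(single$n_sig_snps, 1L)

  expect_error(merge_islands(data.frame(chrom = "chr1",
                                        pos = c(200, 100))), "sorted")
})

test_that("chained merging equals the transitive-closure oracle", {
  set.seed(55)
  for (rep in 1:60) {
    pos <- sort(sample.int(5e5, sample(2:40, 1)))
    d <- sample(c(0, 1e3, 2e4, 5e4), 1)
    isl <- merge_islands(data.frame(chrom = "c", pos = pos), d)
    orc <- oracle_merge(pos, d)
    expect_equal(nrow(isl), length(orc))
    expect_equal(isl$start, vapply(orc, `[`, numeric(1), 1))
    expect_equal(isl$end, vapply(orc, `[`, numeric(1), 2))
    # every site in exactly one island
    expect_equal(sum(isl$n_sig_snps), length(pos))
    expect_equal(sort(unlist(isl$member_positions)), pos)
    # islands pairwise separated by more than d
    if (nrow(isl) > 1)
      expect_true(all(isl$start[-1] - isl$end[-nrow(isl)] > d))
    # idempotence: merging the member positions again changes nothing
    again <- merge_islands(data.frame(chrom = "c",
                                      pos = unlist(isl$member_positions)), d)
    expect_equal(again$start, isl$start)
    expect_equal(again$end, isl$end)
  }
})

test_that("island count is non-increasing in the merge distance", {
  set.seed(77)
  pos <- sort(sample.int(2e6, 300))
  counts <- vapply(c(0, 1e4, 5e4, 1e5), function(d)
    nrow(merge_islands(data.frame(chrom = "c", pos = pos), d)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("closest-gene links match the hand-worked promoter arithmetic", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 100000,
                      end = 110000, strand = "+")
  mk_island <- function(s, e) data.frame(island_id = "isl1", chrom = "chr1",
                                         start = s, end = e)
  # island inside the gene body
  inside <- link_closest_gene(mk_island(105000, 105100), genes)
  expect_equal(inside$distance, 0)
  expect_equal(inside$category, "gene_body")
  # 5.5 kb upstream: outside the 5 kb promoter window [95000, 99999]
  far <- link_closest_gene(mk_island(94000, 94500), genes)
  expect_equal(far$distance, 5500)
  expect_equal(far$category, "intergenic")
  # 3.5-4 kb upstream: overlaps the promoter window
  near <- link_closest_gene(mk_island(96000, 96500), genes)
  expect_equal(near$distance, 3500)
  expect_equal(near$category, "promoter")
  # "-" strand gene: promoter window sits right of the TSS (= end)
  gneg <- data.frame(gene_id = "g2", chrom = "chr1", start = 100000,
                     end = 110000, strand = "-")
  dn <- link_closest_gene(mk_island(112000, 112400), gneg)
  expect_equal(dn$category, "promoter")

  nogene <- link_closest_gene(mk_island(1, 10),
                              data.frame(gene_id = "g", chrom = "chr9",
                                         start = 1, end = 2, strand = "+"))
  expect_true(is.na(nogene$gene_id))
})

test_that("closest gene equals an exhaustive all-genes scan", {
  set.seed(91)
  for (rep in 1:25) {
    genes <- simulate_annotation(annotation_sim_config(
      n_genes = 30, chrom_length = 5e5, seed = 1000 + rep))
    s <- sample.int(5e5, 1)
    isl <- data.frame(island_id = "i", chrom = "chr1", start = s,
                      end = min(s + sample.int(2e4, 1), 5e5))
    link <- link_closest_gene(isl, genes)
    orc <- oracle_closest(isl$start, isl$end, genes)
    expect_equal(link$gene_id, orc$gene_id)
    expect_equal(link$distance, orc$distance)
  }
})

test_that("closest-gene distances agree with GenomicRanges", {
  skip_if_not_installed("GenomicRanges")
  set.seed(19)
  genes <- simulate_annotation(annotation_sim_config(
    n_genes = 40, chrom_length = 4e5, seed = 77))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(genes$start,
                                                        genes$end))
  for (rep in 1:10) {
    s <- sample.int(4e5, 1)
    isl <- data.frame(island_id = "i", chrom = "chr1", start = s,
                      end = min(s + 5000, 4e5))
    link <- link_closest_gene(isl, genes)
    near <- GenomicRanges::distanceToNearest(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(isl$start, isl$end)),
      gr)
    expect_equal(link$distance,
                 as.data.frame(near)$distance + (link$distance > 0))
  }
})
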
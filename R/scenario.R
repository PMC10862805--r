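#' Simulate a multi-chromosome scan dataset with genes and optional
#' planted sweeps
#'
#' Builds a small genome with one gene per chromosome (gene body on the
#' "+" strand, TSS facing a clear upstream flank) and simulates a pair of
#' population panels for every chromosome with
#' [simulate_haplotypes()]. For genes listed in `sweep_genes`, a hard
#' sweep (selection in population A) is planted at the midpoint of the
#' 25 kb window upstream of the TSS, so selection signal concentrates
#' exactly where [gene_score()] looks. This is the ground-truth scenario
#' used to calibrate and power-test the cluster enrichment permutation
#' test.
#'
#' @param n_genes number of genes (= chromosomes).
#' @param sweep_genes integer indices of genes whose upstream windows
#'   receive a sweep (default none: a fully neutral genome).
#' @param chrom_length per-chromosome length in bp (default 150 kb).
#' @param gene_length gene-body length (default 20 kb); the gene starts
#'   at `0.6 * chrom_length`.
#' @param window_bp upstream window width used to place sweeps (default
#'   25 kb).
#' @param selection_coefficient s of the planted sweeps (default 0.5).
#' @param hap template [hap_sim_config()] whose per-chromosome fields
#'   (panel size, population size, generations, rates) are reused; its
#'   chromosome-specific fields are overridden. The template raises the
#'   crossover rate so that swept homozygosity tracts truncate within
#'   these short chromosomes instead of being censored at the edges.
#' @param seed integer seed; chromosome i uses `seed * 1000 + i`.
#' @return A list with `genes` (annotation data frame), `panels` (list of
#'   per-chromosome `pop_a`/`pop_b` pairs), `sweep_genes` and
#'   `chrom_length`.
#' @export
simulate_scan_dataset <- function(n_genes = 40L, sweep_genes = integer(0),
                                  chrom_length = 1.5e5, gene_length = 2e4,
                                  window_bp = 25000,
                                  selection_coefficient = 0.5,
                                  hap = hap_sim_config(
                                    n_haplotypes_per_pop = 40,
                                    pop_size = 500, n_generations = 50,
                                    sweep_time = 40,
                                    recombination_rate = 5e-6),
                                  seed = 1L) {
  check_scalar(n_genes, "n_genes", 1, Inf, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  gene_start <- round(0.6 * chrom_length)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sprintf("chr%d", seq_len(n_genes)),
    start = gene_start, end = gene_start + gene_length - 1,
    strand = "+", stringsAsFactors = FALSE)
  genes$tss <- genes$start
  sweep_pos <- gene_start - round(window_bp / 2)
  panels <- lapply(seq_len(n_genes), function(i) {
    sweeping <- i %in% sweep_genes
    cfg <- hap_sim_config(
      n_haplotypes_per_pop = hap$n_haplotypes_per_pop,
      chrom_length = chrom_length,
      mutation_density = hap$mutation_density,
      recombination_rate = hap$recombination_rate,
      n_generations = hap$n_generations,
      sweep_position = if (sweeping) sweep_pos else NULL,
      selection_coefficient = if (sweeping) selection_coefficient else 0,
      sweep_time = hap$sweep_time, pop_size = hap$pop_size,
      founding_fraction = hap$founding_fraction,
      seed = as.integer((as.numeric(seed) * 1000 + i) %% 2147483647),
      chrom = sprintf("chr%d", i))
    simulate_haplotypes(cfg)
  })
  list(genes = as_gene_annotation(genes), panels = panels,
       sweep_genes = sweep_genes, chrom_length = chrom_length)
}
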
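#' Configuration for the gene-annotation simulator
#'
#' Draws gene intervals uniformly on a chromosome with lengths uniform in
#' `[min_gene_length, max_gene_length]` and strands drawn independently
#' ("+" with probability `strand_probability`). Genes may overlap; every
#' gene lies fully inside `[1, chrom_length]`. The transcription start
#' site (TSS) is the start for "+" genes and the end for "-" genes.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp.
#' @param min_gene_length,max_gene_length gene length bounds in bp.
#' @param strand_probability probability of the "+" strand.
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return An object of class `annotation_sim_config`.
#' @seealso [simulate_annotation()]
#' @export
annotation_sim_config <- function(n_genes = 50L, chrom_length = 1e6,
                                  min_gene_length = 1000L,
                                  max_gene_length = 20000L,
                                  strand_probability = 0.5,
                                  chrom = "chr1", seed = 1L) {
  check_scalar(n_genes, "n_genes", 1, Inf, integer = TRUE)
  check_scalar(chrom_length, "chrom_length", 1)
  check_scalar(min_gene_length, "min_gene_length", 1, chrom_length,
               integer = TRUE)
  check_scalar(max_gene_length, "max_gene_length", 1, chrom_length,
               integer = TRUE)
  if (min_gene_length > max_gene_length)
    stop_invalid("min_gene_length must not exceed max_gene_length")
  check_scalar(strand_probability, "strand_probability", 0, 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(n_genes = as.integer(n_genes), chrom_length = chrom_length,
         min_gene_length = as.integer(min_gene_length),
         max_gene_length = as.integer(max_gene_length),
         strand_probability = strand_probability,
         chrom = as.character(chrom), seed = as.integer(seed)),
    class = "annotation_sim_config")
}

#' Simulate a gene annotation with strand-aware TSSs
#'
#' @param cfg an [annotation_sim_config()].
#' @return A data frame of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `start`, `end` (1-based inclusive), `strand` and `tss`,
#'   sorted by start.
#' @export
#' @examples
#' genes <- simulate_annotation(annotation_sim_config(n_genes = 5, seed = 2))
#' genes
simulate_annotation <- function(cfg) {
  if (!inherits(cfg, "annotation_sim_config"))
    stop_invalid("cfg must be an annotation_sim_config")
  set.seed(cfg$seed)
  len <- if (cfg$min_gene_length == cfg$max_gene_length)
    rep(cfg$min_gene_length, cfg$n_genes)
  else
    sample(seq(cfg$min_gene_length, cfg$max_gene_length), cfg$n_genes,
           replace = TRUE)
  start <- vapply(len, function(l) {
    if (cfg$chrom_length - l + 1 < 1)
      stop_invalid("gene length exceeds chrom_length")
    sample.int(cfg$chrom_length - l + 1, 1L)
  }, numeric(1))
  strand <- ifelse(runif(cfg$n_genes) < cfg$strand_probability, "+", "-")
  g <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = cfg$chrom, start = start, end = start + len - 1,
    strand = strand, stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("gene_annotation", "data.frame")
  g
}

as_gene_annotation <- function(g) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!is.data.frame(g) || !all(need %in% names(g)))
    stop_invalid("genes must be a data frame with columns ",
                 paste(need, collapse = ", "))
  if (any(g$start > g$end)) stop_invalid("gene start must be <= end")
  if (!all(g$strand %in% c("+", "-")))
    stop_invalid("gene strand must be '+' or '-'")
  if (is.null(g$tss)) g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g
}
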
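#' Configuration for the cluster enrichment permutation test
#'
#' @param window_bp width of the scoring window upstream of each TSS
#'   (default 25,000 bp).
#' @param n_iter number of permutation iterations (default 1000).
#' @param gene_summary summary of -log10 p over the SNPs of a window
#'   (`"median"` or `"mean"`; default median).
#' @param cluster_summary summary of gene scores within a cluster
#'   (default median).
#' @param min_snps_per_window windows with fewer scan SNPs than this get
#'   a missing score and are dropped symmetrically from observed and
#'   null pools (default 1).
#' @param exclude_cluster_from_null drop the cluster's own genes from the
#'   null sampling pool (default `FALSE`).
#' @param seed integer seed for the permutation draws.
#' @return An object of class `enrich_config`.
#' @export
enrich_config <- function(window_bp = 25000, n_iter = 1000,
                          gene_summary = c("median", "mean"),
                          cluster_summary = c("median", "mean"),
                          min_snps_per_window = 1,
                          exclude_cluster_from_null = FALSE, seed = 1L) {
  check_scalar(window_bp, "window_bp", 1)
  check_scalar(n_iter, "n_iter", 1, Inf, integer = TRUE)
  check_scalar(min_snps_per_window, "min_snps_per_window", 1,
               integer = TRUE)
  stopifnot(is.logical(exclude_cluster_from_null),
            length(exclude_cluster_from_null) == 1L)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(window_bp = window_bp, n_iter = as.integer(n_iter),
         gene_summary = match.arg(gene_summary),
         cluster_summary = match.arg(cluster_summary),
         min_snps_per_window = as.integer(min_snps_per_window),
         exclude_cluster_from_null = exclude_cluster_from_null,
         seed = as.integer(seed)),
    class = "enrich_config")
}

#' Strand-aware window upstream of each TSS
#'
#' For a "+"-strand gene the window is `[tss - window_bp, tss - 1]`; for a
#' "-"-strand gene, `[tss + 1, tss + window_bp]`. Windows are clipped to
#' `[1, chrom_length]` (when a length is known) and flagged.
#'
#' @param genes gene annotation data frame.
#' @param cfg an [enrich_config()].
#' @param chrom_length optional named vector of chromosome lengths for
#'   right-edge clipping.
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", start = 100000,
#'                 end = 110000, strand = "+")
#' gene_window(g)
gene_window <- function(genes, cfg = enrich_config(), chrom_length = NULL) {
  genes <- as_gene_annotation(genes)
  w <- cfg$window_bp
  start <- ifelse(genes$strand == "+", genes$tss - w, genes$tss + 1)
  end <- ifelse(genes$strand == "+", genes$tss - 1, genes$tss + w)
  clipped <- start < 1
  start <- pmax(start, 1)
  if (!is.null(chrom_length)) {
    len <- if (is.null(names(chrom_length))) rep(chrom_length,
                                                 nrow(genes)) else
      chrom_length[genes$chrom]
    clipped <- clipped | end > len
    end <- pmin(end, len)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, start = start,
             end = pmax(end, start), clipped = clipped)
}

#' Selection-signal score of gene windows
#'
#' The per-gene score is the summary (median by default) of `logp` over
#' the scan SNPs falling in the gene's upstream window; genes with fewer
#' than `cfg$min_snps_per_window` SNPs get `NA`.
#'
#' @param windows output of [gene_window()].
#' @param records an [xpehh_scan()] data frame sorted by position.
#' @param cfg an [enrich_config()].
#' @return Named numeric vector of scores (NA = unscored).
#' @export
gene_score <- function(windows, records, cfg = enrich_config()) {
  summ <- match.fun(cfg$gene_summary)
  scores <- vapply(seq_len(nrow(windows)), function(i) {
    sel <- records$chrom == windows$chrom[i] &
      records$pos >= windows$start[i] & records$pos <= windows$end[i]
    if (sum(sel) < cfg$min_snps_per_window) return(NA_real_)
    summ(records$logp[sel])
  }, numeric(1))
  setNames(scores, windows$gene_id)
}

#' Permutation enrichment test of selection signal in one gene cluster
#'
#' The observed statistic is the cluster-level summary (median by
#' default) of the window scores of the cluster's scored genes (m genes).
#' The null resamples, `n_iter` times, m genes uniformly without
#' replacement from the genome-wide scored gene pool -- their windows
#' have the same fixed width, so the null windows are size-matched by
#' construction -- and applies the same summary. The one-sided
#' (greater) empirical p-value uses the plus-one correction
#' `(1 + #\{null >= observed\}) / (1 + n_iter)`, so it is never 0.
#'
#' @param cluster_genes gene ids of the cluster under test.
#' @param scores genome-wide gene scores from [gene_score()].
#' @param cfg an [enrich_config()].
#' @param cluster_id label carried into the result (default `NA`).
#' @return An object of class `enrichment_result`: a list with
#'   `cluster_id`, `n_genes_scored`, `observed_stat`, `null_stats`
#'   (length `n_iter`), `empirical_p` and `direction = "greater"`.
#' @export
cluster_enrichment_test <- function(cluster_genes, scores,
                                    cfg = enrich_config(),
                                    cluster_id = NA) {
  if (length(cluster_genes) == 0L) stop_invalid("cluster is empty")
  scored <- scores[!is.na(scores)]
  cl <- scored[intersect(names(scored), cluster_genes)]
  if (length(cl) == 0L)
    stop_invalid("no cluster gene has a non-missing score")
  m <- length(cl)
  pool <- if (cfg$exclude_cluster_from_null)
    scored[setdiff(names(scored), cluster_genes)] else scored
  if (length(pool) < m)
    stop_invalid("genome-wide scored gene pool smaller than the cluster")
  summ <- match.fun(cfg$cluster_summary)
  observed <- summ(cl)
  set.seed(cfg$seed)
  null_stats <- vapply(seq_len(cfg$n_iter), function(i) {
    summ(pool[sample.int(length(pool), m)])
  }, numeric(1))
  structure(
    list(cluster_id = cluster_id, n_genes_scored = m,
         observed_stat = observed, null_stats = null_stats,
         empirical_p = (1 + sum(null_stats >= observed)) /
           (1 + cfg$n_iter),
         direction = "greater"),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> cluster %s: %d genes scored, observed %.3f, empirical p = %.4g (one-sided greater, %d iterations)\n",
    as.character(x$cluster_id), x$n_genes_scored, x$observed_stat,
    x$empirical_p, length(x$null_stats)))
  invisible(x)
}

#' Enrichment test applied to every expression cluster
#'
#' @param assignment named cluster labels per gene (e.g. from
#'   [cluster_profiles()]).
#' @param genes gene annotation covering the genome-wide pool.
#' @param records an [xpehh_scan()] data frame.
#' @param cfg an [enrich_config()]; each cluster's permutations use
#'   `cfg$seed + <cluster index>` so the table is reproducible.
#' @param chrom_length optional chromosome lengths for window clipping.
#' @return A data frame with one row per cluster (`cluster_id`,
#'   `n_genes_scored`, `observed_stat`, `empirical_p`, `padj_bh`) and the
#'   per-cluster `enrichment_result`s in attribute `"results"`.
#' @export
enrichment_by_cluster <- function(assignment, genes, records,
                                  cfg = enrich_config(),
                                  chrom_length = NULL) {
  windows <- gene_window(genes, cfg, chrom_length)
  scores <- gene_score(windows, records, cfg)
  ids <- sort(unique(assignment))
  results <- lapply(seq_along(ids), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    # a cluster whose genes all lack scan SNPs is reported as NA, not fatal
    tryCatch(
      cluster_enrichment_test(names(assignment)[assignment == ids[i]],
                              scores, cfg_i, cluster_id = ids[i]),
      error = function(e) structure(
        list(cluster_id = ids[i], n_genes_scored = 0L,
             observed_stat = NA_real_, null_stats = numeric(0),
             empirical_p = NA_real_, direction = "greater"),
        class = "enrichment_result"))
  })
  out <- data.frame(
    cluster_id = ids,
    n_genes_scored = vapply(results, function(r)
      as.integer(r$n_genes_scored), integer(1)),
    observed_stat = vapply(results, `[[`, numeric(1), "observed_stat"),
    empirical_p = vapply(results, `[[`, numeric(1), "empirical_p"))
  out$padj_bh <- p.adjust(out$empirical_p, method = "BH")
  attr(out, "results") <- results
  out
}
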
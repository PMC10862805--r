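#' Median-of-ratios size factors
#'
#' The reference for each gene is its geometric mean across samples
#' (genes with any zero count are excluded); a sample's size factor is
#' the median over included genes of the ratio of its count to the
#' reference.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
#' @examples
#' size_factors(matrix(c(2, 8, 4, 16), 2, 2))
size_factors <- function(counts) {
  counts <- .check_counts(counts)
  keep <- rowSums(counts == 0) == 0L
  if (!any(keep))
    stop_invalid("normalization impossible: no gene has nonzero counts in every sample")
  ref <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  f <- apply(counts[keep, , drop = FALSE] / ref, 2, median)
  setNames(f, colnames(counts))
}

.check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts) || length(counts) == 0L)
    stop_invalid("counts must be a non-empty numeric matrix")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop_invalid("counts must be finite and non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  counts
}

.check_meta <- function(counts, meta) {
  need <- c("sample_id", "species", "stage", "replicate")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop_invalid("meta must have columns ", paste(need, collapse = ", "))
  if (is.null(colnames(counts)) ||
      !setequal(colnames(counts), meta$sample_id) ||
      anyDuplicated(meta$sample_id))
    stop_invalid("meta$sample_id must match colnames(counts) exactly once each")
  meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
}

#' Filter genes with uniformly low raw counts
#'
#' A gene is removed iff, within each species separately, every sample
#' has a raw count below `min_count` (`mode = "both"`, the default
#' reading of "counts < 10 per sample in each species"); with
#' `mode = "either"` a gene is removed as soon as one species has all
#' counts below the threshold.
#'
#' @param counts raw count matrix, genes x samples.
#' @param meta sample metadata (`sample_id`, `species`, `stage`,
#'   `replicate`).
#' @param min_count threshold (default 10; the bound is strict, so a
#'   single count equal to `min_count` retains the gene).
#' @param mode `"both"` or `"either"`; see above.
#' @return Character vector of retained gene ids.
#' @export
low_count_filter <- function(counts, meta, min_count = 10,
                             mode = c("both", "either")) {
  counts <- .check_counts(counts)
  meta <- .check_meta(counts, meta)
  mode <- match.arg(mode)
  check_scalar(min_count, "min_count", 0)
  low <- vapply(unique(meta$species), function(sp) {
    cols <- meta$sample_id[meta$species == sp]
    apply(counts[, cols, drop = FALSE] < min_count, 1, all)
  }, logical(nrow(counts)))
  removed <- if (mode == "both") apply(low, 1, all) else apply(low, 1, any)
  rownames(counts)[!removed]
}

#' Between-group negative-binomial Wald test
#'
#' A transparent stand-in for a full shrinkage-based differential
#' expression fit: counts are normalized by the size factors, group means
#' are compared on the log scale with
#' `log2fc = log2((m2 + 0.5) / (m1 + 0.5))`, the per-gene overdispersion
#' alpha (variance `mu + alpha * mu^2`) is estimated by the method of
#' moments from the pooled within-group variances and moderated toward
#' the genome-wide central value (genes provide only a few residual
#' degrees of freedom each, so unmoderated gene-wise estimates make the
#' Wald test anticonservative), and the delta-method Wald statistic on
#' the log-mean difference is referred to the standard normal, two
#' sided, with Benjamini-Hochberg adjustment across genes.
#'
#' @param counts raw count matrix, genes x samples.
#' @param factors size factors from [size_factors()].
#' @param meta sample metadata.
#' @param contrast list with `group1` and `group2` (sample id vectors,
#'   each of size >= 2) and optionally `name`; see
#'   [species_stage_contrasts()].
#' @param moderation_df prior degrees of freedom pulling gene-wise
#'   dispersion estimates toward their genome-wide median (default 20).
#' @return Data frame with columns `gene_id`, `contrast`, `log2fc`,
#'   `pvalue`, `padj`.
#' @export
de_contrast <- function(counts, factors, meta, contrast,
                        moderation_df = 20) {
  counts <- .check_counts(counts)
  meta <- .check_meta(counts, meta)
  g1 <- contrast$group1
  g2 <- contrast$group2
  if (length(g1) < 2L || length(g2) < 2L)
    stop_invalid("each group needs >= 2 replicates")
  if (!all(c(g1, g2) %in% colnames(counts)))
    stop_invalid("contrast samples missing from counts")
  norm <- sweep(counts[, c(g1, g2), drop = FALSE], 2,
                factors[c(g1, g2)], "/")
  x1 <- norm[, g1, drop = FALSE]
  x2 <- norm[, g2, drop = FALSE]
  if (all(x1 == 0) || all(x2 == 0))
    stop_invalid("degenerate contrast: a group has all-zero counts")
  n1 <- length(g1)
  n2 <- length(g2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  vw <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  mw <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha_gene <- pmax((vw - mw) / pmax(mw, 0.5)^2, 1e-8)
  alpha_central <- median(alpha_gene)
  df_gene <- n1 + n2 - 2L
  alpha <- pmax((moderation_df * alpha_central + df_gene * alpha_gene) /
                  (moderation_df + df_gene), 1e-8)
  se2 <- (1 / (m1 + 0.5) + alpha) / n1 + (1 / (m2 + 0.5) + alpha) / n2
  wald <- (log(m2 + 0.5) - log(m1 + 0.5)) / sqrt(se2)
  pvalue <- 2 * pnorm(-abs(wald))
  data.frame(
    gene_id = rownames(counts),
    contrast = if (is.null(contrast$name)) "group2_vs_group1" else
      contrast$name,
    log2fc = log2((m2 + 0.5) / (m1 + 0.5)),
    pvalue = pvalue,
    padj = p.adjust(pvalue, method = "BH"),
    row.names = NULL)
}

#' Between-species contrasts of a developmental design
#'
#' @param meta sample metadata.
#' @param cross_stage if `TRUE`, also pair every stage of species A with
#'   every other stage of species B; the default compares the two species
#'   at each shared stage.
#' @return List of contrasts usable with [de_contrast()].
#' @export
species_stage_contrasts <- function(meta, cross_stage = FALSE) {
  sp <- sort(unique(meta$species))
  if (length(sp) != 2L) stop_invalid("meta must contain exactly 2 species")
  stages_a <- sort(unique(meta$stage[meta$species == sp[1L]]))
  stages_b <- sort(unique(meta$stage[meta$species == sp[2L]]))
  pairs <- if (cross_stage) expand.grid(a = stages_a, b = stages_b) else {
    shared <- intersect(stages_a, stages_b)
    data.frame(a = shared, b = shared)
  }
  lapply(seq_len(nrow(pairs)), function(i) {
    list(group1 = meta$sample_id[meta$species == sp[1L] &
                                   meta$stage == pairs$a[i]],
         group2 = meta$sample_id[meta$species == sp[2L] &
                                   meta$stage == pairs$b[i]],
         name = sprintf("%s_s%s_vs_%s_s%s", sp[2L], pairs$b[i], sp[1L],
                        pairs$a[i]))
  })
}

#' Call differentially expressed genes across contrasts
#'
#' A record is a DEG call iff `|log2fc| >= lfc_threshold` (inclusive;
#' 0.585 is log2 of a 1.5-fold difference) and `padj < alpha`. The DEG
#' set is the union over contrasts: a gene passing in at least one
#' pairwise comparison.
#'
#' @param records row-bound [de_contrast()] results.
#' @param lfc_threshold absolute log2 fold-change bound (default 0.585).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return A list with `records` (input plus logical `is_deg`) and
#'   `deg_genes` (character vector, the union over contrasts).
#' @export
call_degs <- function(records, lfc_threshold = 0.585, alpha = 0.05) {
  if (!is.data.frame(records) ||
      !all(c("gene_id", "log2fc", "padj") %in% names(records)))
    stop_invalid("records must have columns gene_id, log2fc, padj")
  check_scalar(lfc_threshold, "lfc_threshold", 0)
  check_scalar(alpha, "alpha", 0, 1)
  records$is_deg <- abs(records$log2fc) >= lfc_threshold &
    records$padj < alpha
  list(records = records,
       deg_genes = sort(unique(records$gene_id[records$is_deg])))
}

#' Z-scored temporal expression profiles
#'
#' Per gene: the mean normalized count in each (species, stage) cell,
#' Z-scored across the gene's profile vector. Genes with zero profile
#' variance get an all-zero profile and are flagged for exclusion from
#' clustering.
#'
#' @param counts raw count matrix.
#' @param factors size factors.
#' @param meta sample metadata.
#' @param genes gene ids to profile (default all).
#' @return A list with `z` (genes x (species x stage) matrix, columns
#'   named `<species>_s<stage>`) and `excluded` (logical, zero-variance
#'   genes).
#' @export
stage_profiles <- function(counts, factors, meta, genes = rownames(counts)) {
  counts <- .check_counts(counts)
  meta <- .check_meta(counts, meta)
  genes <- intersect(genes, rownames(counts))
  if (length(genes) == 0L) stop_invalid("no genes to profile")
  norm <- sweep(counts[genes, , drop = FALSE], 2, factors[colnames(counts)],
                "/")
  cell <- interaction(meta$species, meta$stage, sep = "_s", drop = TRUE)
  cells <- levels(cell)
  prof <- vapply(cells, function(cl) {
    rowMeans(norm[, meta$sample_id[cell == cl], drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1L) prof <- matrix(prof, 1L,
                                          dimnames = list(genes, cells))
  mu <- rowMeans(prof)
  s <- apply(prof, 1, sd)
  excluded <- s == 0
  z <- (prof - mu) / ifelse(s == 0, 1, s)
  z[excluded, ] <- 0
  list(z = z, excluded = setNames(excluded, genes))
}

#' Complete-linkage clustering of Z-profiles
#'
#' Agglomerative hierarchical clustering with complete linkage and
#' Euclidean distance on the Z-scored profiles, cut at `k` clusters.
#' Excluded (zero-variance) genes are dropped before clustering. Output
#' is deterministic given the input; equal-height merge ties are resolved
#' by `stats::hclust`'s ordering, so cluster labels are defined up to
#' relabeling under row permutation.
#'
#' @param profiles output of [stage_profiles()] (or a plain Z matrix).
#' @param k number of clusters (default 7).
#' @return A list with `assignment` (named integer vector in 1..k),
#'   `centroids` (k x cells mean-profile matrix), `sizes` and the
#'   `hclust` tree.
#' @export
cluster_profiles <- function(profiles, k = 7) {
  check_scalar(k, "k", 1, Inf, integer = TRUE)
  z <- if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles$z[!profiles$excluded, , drop = FALSE]
  } else {
    as.matrix(profiles)
  }
  if (nrow(z) < k)
    stop_invalid("need at least k = ", k, " non-excluded genes, got ",
                 nrow(z))
  hc <- stats::hclust(stats::dist(z), method = "complete")
  assignment <- stats::cutree(hc, k = k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(cl) {
    colMeans(z[assignment == cl, , drop = FALSE])
  }))
  rownames(centroids) <- paste0("cluster", seq_len(k))
  list(assignment = assignment, centroids = centroids,
       sizes = as.integer(table(assignment)), tree = hc)
}
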
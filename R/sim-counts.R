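#' Default temporal-profile archetypes for the count simulator
#'
#' Seven mean log2-expression profiles over a (species x stage) design,
#' emulating the qualitative cluster shapes seen in two-species
#' developmental time courses: four clusters with a consistent
#' between-species offset across all stages (two flat, two with a shared
#' temporal trend) and three with species-specific temporal shifts
#' (early/late/mid peaks occurring at different times in the two species).
#' Values are unitless multipliers of `effect_size_log2`, roughly in
#' \[-0.5, 0.5\].
#'
#' @param n_stages number of developmental stages.
#' @return Matrix with 7 rows and `2 * n_stages` columns; columns are
#'   ordered species A stages 1..n then species B stages 1..n.
#' @export
default_archetypes <- function(n_stages = 10L) {
  t <- seq(0, 1, length.out = n_stages)
  bump <- function(center, width = 0.18) exp(-((t - center) / width)^2) - 0.5
  a <- rbind(
    c(bump(0.15), bump(0.85)),            # temporal shift: A early, B late
    c(rep(0.5, n_stages), rep(-0.5, n_stages)),   # A high, B low, flat
    c(rep(-0.5, n_stages), rep(0.5, n_stages)),   # A low, B high, flat
    c(bump(0.85), bump(0.15)),            # temporal shift: A late, B early
    c(t - 0.5 + 0.4, t - 0.5 - 0.4),      # shared rising trend, A offset high
    c(0.5 - t - 0.4, 0.5 - t + 0.4),      # shared falling trend, B offset high
    c(bump(0.5), rep(0, n_stages)))       # mid peak in A, flat in B
  rownames(a) <- paste0("cluster", 1:7)
  a
}

#' Configuration for the clustered negative-binomial count simulator
#'
#' Generates a raw gene x sample count matrix for a two-species
#' developmental time course with known cluster structure: each gene is
#' assigned one of `n_clusters` temporal-profile archetypes; its counts are
#' drawn from a negative-binomial distribution with mean
#' `2^(base_log2 + effect_size_log2 * archetype + replicate noise)` scaled
#' by a per-sample library-size factor drawn log-uniformly in \[0.5, 2\]
#' (so median-of-ratios recovery is testable).
#'
#' @param n_genes number of genes.
#' @param n_clusters number of planted archetypes (default 7).
#' @param n_stages developmental stages per species (default 10).
#' @param n_replicates biological replicates per (species, stage) (default
#'   3).
#' @param nb_dispersion per-gene overdispersion alpha > 0, with
#'   `variance = mu + alpha * mu^2`; the Poisson limit is alpha -> 0.
#'   Scalar or one value per gene.
#' @param cluster_archetypes `n_clusters x (2 * n_stages)` matrix of mean
#'   log2 profiles; defaults to [default_archetypes()] (requires
#'   `n_clusters = 7`).
#' @param effect_size_log2 multiplier of the archetype profiles; 0 gives a
#'   between-species null.
#' @param base_log2 genome-wide mean log2 expression (default 7, i.e.
#'   about 128 counts).
#' @param replicate_sd standard deviation of per-observation log2 noise.
#' @param seed integer seed.
#'
#' @return An object of class `counts_sim_config`.
#' @seealso [simulate_counts()]
#' @export
counts_sim_config <- function(n_genes = 700L, n_clusters = 7L,
                              n_stages = 10L, n_replicates = 3L,
                              nb_dispersion = 0.05,
                              cluster_archetypes = NULL,
                              effect_size_log2 = 2, base_log2 = 7,
                              replicate_sd = 0.1, seed = 1L) {
  check_scalar(n_genes, "n_genes", 1, Inf, integer = TRUE)
  check_scalar(n_clusters, "n_clusters", 1, Inf, integer = TRUE)
  check_scalar(n_stages, "n_stages", 1, Inf, integer = TRUE)
  check_scalar(n_replicates, "n_replicates", 1, Inf, integer = TRUE)
  if (!is.numeric(nb_dispersion) ||
      !length(nb_dispersion) %in% c(1L, n_genes) ||
      any(!is.finite(nb_dispersion)) || any(nb_dispersion <= 0))
    stop_invalid("nb_dispersion must be positive (scalar or one per gene)")
  if (is.null(cluster_archetypes)) {
    if (n_clusters != 7L)
      stop_invalid("supply cluster_archetypes when n_clusters != 7")
    cluster_archetypes <- default_archetypes(n_stages)
  }
  if (!is.matrix(cluster_archetypes) ||
      nrow(cluster_archetypes) != n_clusters ||
      ncol(cluster_archetypes) != 2L * n_stages)
    stop_invalid("cluster_archetypes must be n_clusters x (2 * n_stages)")
  check_scalar(effect_size_log2, "effect_size_log2", 0)
  check_scalar(base_log2, "base_log2")
  check_scalar(replicate_sd, "replicate_sd", 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(n_genes = as.integer(n_genes), n_clusters = as.integer(n_clusters),
         n_stages = as.integer(n_stages), n_species = 2L,
         n_replicates = as.integer(n_replicates),
         nb_dispersion = nb_dispersion,
         cluster_archetypes = cluster_archetypes,
         effect_size_log2 = effect_size_log2, base_log2 = base_log2,
         replicate_sd = replicate_sd, seed = as.integer(seed)),
    class = "counts_sim_config")
}

#' Simulate a clustered two-species developmental count matrix
#'
#' @param cfg a [counts_sim_config()].
#' @return A list with `counts` (integer matrix, genes x samples), `meta`
#'   (data frame with `sample_id`, `species` in \{A, B\}, `stage`,
#'   `replicate`), `cluster` (true archetype label per gene) and
#'   `size_factors_true` (the planted library-size factors).
#' @export
#' @examples
#' sim <- simulate_counts(counts_sim_config(n_genes = 70, seed = 3))
#' dim(sim$counts)
#' table(sim$cluster)
simulate_counts <- function(cfg) {
  if (!inherits(cfg, "counts_sim_config"))
    stop_invalid("cfg must be a counts_sim_config")
  set.seed(cfg$seed)
  ns <- cfg$n_stages
  meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      stage = seq_len(ns), species = c("A", "B"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("species", "stage", "replicate")]
  meta$sample_id <- sprintf("%s_s%02d_r%d", meta$species, meta$stage,
                            meta$replicate)
  n_samp <- nrow(meta)

  cluster <- sample(rep_len(seq_len(cfg$n_clusters), cfg$n_genes))
  sf <- 2^runif(n_samp, log2(0.5), log2(2))
  # archetype column for each sample: species block, then stage
  arch_col <- (match(meta$species, c("A", "B")) - 1L) * ns + meta$stage
  alpha <- rep_len(cfg$nb_dispersion, cfg$n_genes)

  log2mu <- cfg$base_log2 +
    cfg$effect_size_log2 * cfg$cluster_archetypes[cluster, arch_col,
                                                  drop = FALSE] +
    matrix(rnorm(cfg$n_genes * n_samp, sd = cfg$replicate_sd),
           cfg$n_genes, n_samp)
  mu <- sweep(2^log2mu, 2, sf, "*")
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = rep(1 / alpha, n_samp)),
    cfg$n_genes, n_samp)
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("gene%04d", seq_len(cfg$n_genes))
  colnames(counts) <- meta$sample_id

  list(counts = counts,
       meta = meta[, c("sample_id", "species", "stage", "replicate")],
       cluster = setNames(cluster, rownames(counts)),
       size_factors_true = setNames(sf, meta$sample_id))
}
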
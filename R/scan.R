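#' Configuration for the cross-population haplotype scan
#'
#' @param maf_threshold minor-allele-frequency cutoff; a site is retained
#'   iff its pooled MAF is strictly greater than this (default 0.05).
#' @param ehhs_truncation EHHS level below which integration of the decay
#'   curve stops on each side of the focal site (default 0.05).
#' @param max_gap_bp inter-site gap beyond which a side of the EHHS
#'   profile is censored rather than extended (default 200 kb).
#' @param drop_censored drop sites whose EHHS never fell below the
#'   truncation threshold before a chromosome edge or oversized gap in
#'   either population (default `TRUE`; such sites have downward-biased
#'   integrals).
#' @param per_population_maf apply the MAF filter within each population
#'   separately instead of on the pooled sample (default `FALSE`).
#' @param seed reserved; the scan itself is deterministic.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(maf_threshold = 0.05, ehhs_truncation = 0.05,
                        max_gap_bp = 200000, drop_censored = TRUE,
                        per_population_maf = FALSE, seed = NULL) {
  check_scalar(maf_threshold, "maf_threshold", 0, 0.5 - 1e-12)
  check_scalar(ehhs_truncation, "ehhs_truncation", 1e-12, 1 - 1e-12)
  check_scalar(max_gap_bp, "max_gap_bp", 1)
  stopifnot(is.logical(drop_censored), length(drop_censored) == 1L,
            is.logical(per_population_maf), length(per_population_maf) == 1L)
  check_scalar(seed, "seed", integer = TRUE, allow_null = TRUE)
  structure(
    list(maf_threshold = maf_threshold, ehhs_truncation = ehhs_truncation,
         max_gap_bp = max_gap_bp, drop_censored = drop_censored,
         per_population_maf = per_population_maf, seed = seed),
    class = "scan_config")
}

#' Per-site derived-allele frequency and minor-allele frequency
#'
#' @param H a [haplotype_matrix()].
#' @return Data frame with columns `pos`, `freq` (derived-allele
#'   frequency, the column mean) and `maf = min(freq, 1 - freq)`.
#' @export
site_frequencies <- function(H) {
  assert_haplotype_matrix(H)
  freq <- colMeans(H$alleles)
  data.frame(pos = H$positions, freq = freq, maf = pmin(freq, 1 - freq))
}

#' Sites passing the joint minor-allele-frequency filter
#'
#' Retains a site iff its MAF in the pooled sample of both populations is
#' strictly greater than `cfg$maf_threshold` (or, with
#' `cfg$per_population_maf`, iff both per-population MAFs are).
#'
#' @param A,B [haplotype_matrix()] panels over identical positions.
#' @param cfg a [scan_config()].
#' @return Strictly increasing integer site indices.
#' @export
joint_maf_filter <- function(A, B, cfg = scan_config()) {
  assert_shared_positions(A, B)
  if (cfg$per_population_maf) {
    ok <- site_frequencies(A)$maf > cfg$maf_threshold &
      site_frequencies(B)$maf > cfg$maf_threshold
  } else {
    freq <- colSums(A$alleles) + colSums(B$alleles)
    freq <- freq / (nrow(A$alleles) + nrow(B$alleles))
    ok <- pmin(freq, 1 - freq) > cfg$maf_threshold
  }
  which(ok)
}

#' Site-specific extended haplotype homozygosity profile
#'
#' Starting at a focal site, haplotypes are grouped by their allele string
#' over the closed interval from the focal site out to each successive
#' site x; the unnormalized homozygosity is
#' `h(x) = sum_g C(n_g, 2) / C(n, 2)` over haplotype groups g, and
#' `EHHS(x) = h(x) / h(focal)`, so the profile starts at 1 and is
#' non-increasing outward. Each side stops at a chromosome edge or when
#' the gap to the next site exceeds `cfg$max_gap_bp`; a side is censored
#' if EHHS never fell below `cfg$ehhs_truncation` before stopping.
#'
#' @param H a [haplotype_matrix()] with at least 4 haplotypes.
#' @param focal_index column index of the focal site.
#' @param cfg a [scan_config()] (supplies the truncation threshold used
#'   for the censoring flags and the maximum gap).
#' @return An object of class `ehhs_profile` with elements `focal_index`,
#'   `left_values`/`right_values` (each starting with the focal value 1),
#'   `left_positions`/`right_positions`, `censored_left`,
#'   `censored_right`.
#' @export
ehhs_profile <- function(H, focal_index, cfg = scan_config()) {
  assert_haplotype_matrix(H)
  if (n_haplotypes(H) < 4L)
    stop_invalid("at least 4 haplotypes are required")
  check_scalar(focal_index, "focal_index", 1, n_sites(H), integer = TRUE)
  res <- ehhs_profile_cpp(H$alleles, H$positions, as.integer(focal_index) - 1L,
                          cfg$ehhs_truncation, cfg$max_gap_bp, FALSE)
  structure(
    list(focal_index = as.integer(focal_index),
         left_values = c(1, res$left_values),
         left_positions = c(H$positions[focal_index],
                            H$positions[res$left_indices + 1L]),
         right_values = c(1, res$right_values),
         right_positions = c(H$positions[focal_index],
                             H$positions[res$right_indices + 1L]),
         censored_left = res$censored_left,
         censored_right = res$censored_right),
    class = "ehhs_profile")
}

#' @export
print.ehhs_profile <- function(x, ...) {
  cat(sprintf(
    "<ehhs_profile> focal site %d: %d sites left (censored: %s), %d right (censored: %s)\n",
    x$focal_index, length(x$left_values) - 1L, x$censored_left,
    length(x$right_values) - 1L, x$censored_right))
  invisible(x)
}

# trapezoid under one side of a profile out to (and including) the first
# sub-threshold value
.side_area <- function(values, positions, trunc) {
  area <- 0
  if (length(values) < 2L) return(area)
  for (j in 2:length(values)) {
    area <- area + 0.5 * (values[j - 1L] + values[j]) *
      abs(positions[j] - positions[j - 1L])
    if (values[j] < trunc) break
  }
  area
}

#' Integrate an EHHS profile into iES
#'
#' Trapezoidal integration of EHHS against bp position on each side of the
#' focal site, proceeding outward until EHHS drops below
#' `cfg$ehhs_truncation`; the first sub-threshold site terminates that side
#' but still contributes its trapezoid. A censored side (threshold never
#' reached) is integrated in full and flagged.
#'
#' @param p an [ehhs_profile()].
#' @param cfg a [scan_config()].
#' @return A list with `ies` (bp units; 0 for a single-site profile) and
#'   `censored`.
#' @export
integrate_ies <- function(p, cfg = scan_config()) {
  if (!inherits(p, "ehhs_profile")) stop_invalid("p must be an ehhs_profile")
  list(ies = .side_area(p$left_values, p$left_positions,
                        cfg$ehhs_truncation) +
         .side_area(p$right_values, p$right_positions, cfg$ehhs_truncation),
       censored = p$censored_left || p$censored_right)
}

#' Genome-wide standardization of raw xpEHH and -log10 p-values
#'
#' `z = (raw - mean(raw)) / sd(raw)` over the retained, uncensored sites,
#' and `logp = -log10(2 * (1 - Phi(|z|)))`, the two-sided standard-normal
#' p-value of the standardized statistic.
#'
#' @param raw numeric vector of raw xpEHH values (`ln(iES_A / iES_B)`).
#' @return A list with `z` and `logp`.
#' @export
standardize_and_logp <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop_invalid("raw xpEHH values must be finite")
  if (length(unique(raw)) < 2L)
    stop_invalid("degenerate distribution: need >= 2 distinct raw values")
  s <- sd(raw)
  if (s == 0) stop_invalid("degenerate distribution: zero variance")
  z <- (raw - mean(raw)) / s
  logp <- -(log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)) / log(10)
  list(z = z, logp = logp)
}

# per-site iES in both populations at the retained sites; no standardization
.raw_records <- function(A, B, cfg) {
  assert_shared_positions(A, B)
  if (n_haplotypes(A) < 4L || n_haplotypes(B) < 4L)
    stop_invalid("at least 4 haplotypes per population are required")
  idx <- joint_maf_filter(A, B, cfg)
  if (length(idx) == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      maf_A = numeric(), maf_B = numeric(),
                      iES_A = numeric(), iES_B = numeric(),
                      xpehh_raw = numeric(), censored = logical()))
  ia <- ies_scan_cpp(A$alleles, A$positions, as.integer(idx) - 1L,
                     cfg$ehhs_truncation, cfg$max_gap_bp)
  ib <- ies_scan_cpp(B$alleles, B$positions, as.integer(idx) - 1L,
                     cfg$ehhs_truncation, cfg$max_gap_bp)
  fa <- colMeans(A$alleles[, idx, drop = FALSE])
  fb <- colMeans(B$alleles[, idx, drop = FALSE])
  rec <- data.frame(
    chrom = A$chrom, pos = A$positions[idx],
    maf_A = pmin(fa, 1 - fa), maf_B = pmin(fb, 1 - fb),
    iES_A = ia$ies, iES_B = ib$ies,
    censored = ia$censored | ib$censored)
  keep <- rec$iES_A > 0 & rec$iES_B > 0
  if (cfg$drop_censored) keep <- keep & !rec$censored
  rec <- rec[keep, , drop = FALSE]
  rec$xpehh_raw <- log(rec$iES_A / rec$iES_B)
  rownames(rec) <- NULL
  rec
}

.finish_scan <- function(rec) {
  if (nrow(rec) == 0L) {
    warning("no sites survived filtering; returning an empty scan")
    rec$z <- numeric(0)
    rec$logp <- numeric(0)
    return(.as_scan(rec))
  }
  std <- standardize_and_logp(rec$xpehh_raw)
  rec$z <- std$z
  rec$logp <- std$logp
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  .as_scan(rec)
}

.as_scan <- function(rec) {
  cols <- c("chrom", "pos", "maf_A", "maf_B", "iES_A", "iES_B",
            "xpehh_raw", "z", "logp", "censored")
  rec <- rec[, cols, drop = FALSE]
  class(rec) <- c("xpehh_scan", "data.frame")
  rec
}

#' Cross-population extended haplotype homozygosity scan
#'
#' For each site passing the pooled MAF filter, computes the bp-weighted
#' integral iES of the EHHS decay curve in each population and the raw
#' statistic `xpehh_raw = ln(iES_A / iES_B)`; positive values indicate
#' longer haplotype homozygosity in population A (the first argument).
#' Sites with a zero integral in either population, or censored profiles
#' when `cfg$drop_censored`, are excluded before genome-wide
#' standardization into `z` and two-sided `-log10` p-values.
#'
#' @param A,B [haplotype_matrix()] panels over identical positions;
#'   population A is the numerator of the ratio.
#' @param cfg a [scan_config()].
#' @return A data frame of class `xpehh_scan`, sorted by (chrom, pos),
#'   with columns `chrom`, `pos`, `maf_A`, `maf_B`, `iES_A`, `iES_B`,
#'   `xpehh_raw`, `z`, `logp`, `censored`.
#' @export
#' @examples
#' sim <- simulate_haplotypes(hap_sim_config(
#'   n_haplotypes_per_pop = 20, chrom_length = 2e5, n_sites = 400,
#'   pop_size = 80, n_generations = 40, seed = 5))
#' scan <- xpehh_scan(sim$pop_a, sim$pop_b)
#' head(scan)
xpehh_scan <- function(A, B, cfg = scan_config()) {
  .finish_scan(.raw_records(A, B, cfg))
}

#' Multi-chromosome scan with genome-wide standardization
#'
#' Runs the per-site iES computation on each pair of panels and
#' standardizes the pooled raw xpEHH values once, so p-values are
#' comparable genome wide.
#'
#' @param panel_pairs list of lists with elements `pop_a` and `pop_b`
#'   (e.g. outputs of [simulate_haplotypes()]), one per chromosome.
#' @param cfg a [scan_config()].
#' @return A data frame of class `xpehh_scan` over all chromosomes.
#' @export
xpehh_scan_multi <- function(panel_pairs, cfg = scan_config()) {
  recs <- lapply(panel_pairs, function(p) .raw_records(p$pop_a, p$pop_b, cfg))
  .finish_scan(do.call(rbind, recs))
}
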
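#' Phased haplotype panel for one population on one chromosome
#'
#' Container for a matrix of phased binary alleles (rows = haplotypes,
#' columns = segregating sites) with strictly increasing 1-based bp
#' positions. This is the unit of input of the selection scan: one panel
#' per population, sharing an identical position vector.
#'
#' @param alleles integer matrix over \{0, 1\}, haplotypes x sites.
#' @param positions strictly increasing 1-based bp coordinates, one per
#'   column of `alleles`.
#' @param chrom chromosome identifier.
#' @param population population label carried through to scan output.
#'
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `chrom`, `positions`, `alleles` and `population_label`.
#' @export
#' @examples
#' h <- haplotype_matrix(matrix(c(0L, 1L, 0L, 1L), 4, 1), positions = 500)
#' site_frequencies(h)
haplotype_matrix <- function(alleles, positions, chrom = "chr1",
                             population = "pop") {
  if (!is.matrix(alleles) || length(alleles) == 0L)
    stop_invalid("alleles must be a non-empty matrix")
  storage.mode(alleles) <- "integer"
  if (any(is.na(alleles)) || !all(alleles %in% c(0L, 1L)))
    stop_invalid("alleles must contain only 0 and 1")
  positions <- as.numeric(positions)
  if (length(positions) != ncol(alleles))
    stop_invalid("length(positions) must equal ncol(alleles)")
  if (any(!is.finite(positions)) || any(positions < 1))
    stop_invalid("positions must be finite and >= 1")
  if (ncol(alleles) > 1L && any(diff(positions) <= 0))
    stop_invalid("positions must be strictly increasing")
  structure(
    list(chrom = as.character(chrom), positions = positions,
         alleles = alleles, population_label = as.character(population)),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<haplotype_matrix> %s, population %s: %d haplotypes x %d sites (%.0f-%.0f bp)\n",
    x$chrom, x$population_label, nrow(x$alleles), ncol(x$alleles),
    min(x$positions), max(x$positions)))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

n_haplotypes <- function(h) nrow(h$alleles)
n_sites <- function(h) ncol(h$alleles)

assert_haplotype_matrix <- function(h, name = "H") {
  if (!inherits(h, "haplotype_matrix"))
    stop_invalid(name, " must be a haplotype_matrix")
  invisible(h)
}

assert_shared_positions <- function(a, b) {
  assert_haplotype_matrix(a, "A")
  assert_haplotype_matrix(b, "B")
  if (!identical(a$chrom, b$chrom) ||
      length(a$positions) != length(b$positions) ||
      any(a$positions != b$positions))
    stop_invalid("the two panels must share identical chromosome and positions")
  invisible(NULL)
}
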
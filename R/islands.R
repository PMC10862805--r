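#' Significant sites of a scan
#'
#' Retains scan records with `logp >= logp_threshold` (inclusive bound).
#'
#' @param records an [xpehh_scan()] data frame (or any data frame with
#'   `chrom`, `pos`, `logp`), sorted by (chrom, pos).
#' @param logp_threshold -log10 p cutoff (default 3).
#' @return The retained records.
#' @export
significant_sites <- function(records, logp_threshold = 3) {
  if (!is.data.frame(records) ||
      !all(c("chrom", "pos", "logp") %in% names(records)))
    stop_invalid("records must have columns chrom, pos, logp")
  check_scalar(logp_threshold, "logp_threshold", 0)
  out <- records[records$logp >= logp_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge significant sites into selection islands
#'
#' Single left-to-right pass per chromosome: a site joins the current
#' island iff its distance to the island's last member is at most
#' `merge_distance` (chained merging, the semantics of
#' `bedtools merge -d`). Island start/end are the min/max member
#' positions.
#'
#' @param sites data frame with columns `chrom`, `pos` (sorted, unique
#'   within chromosome) and optionally `logp`.
#' @param merge_distance maximum bp gap between consecutive members
#'   (default 50,000).
#' @return A data frame of class `selection_islands` with columns
#'   `island_id`, `chrom`, `start`, `end` (1-based inclusive),
#'   `n_sig_snps`, `max_logp`, `mean_logp` and a list column
#'   `member_positions`.
#' @export
#' @examples
#' sites <- data.frame(chrom = "chr1", pos = c(100, 40000, 120000),
#'                     logp = c(3, 4, 5))
#' merge_islands(sites, merge_distance = 50000)
merge_islands <- function(sites, merge_distance = 50000) {
  if (!is.data.frame(sites) || !all(c("chrom", "pos") %in% names(sites)))
    stop_invalid("sites must have columns chrom, pos")
  check_scalar(merge_distance, "merge_distance", 0)
  if (is.null(sites$logp)) sites$logp <- NA_real_
  out <- lapply(split(sites, sites$chrom), function(s) {
    if (nrow(s) > 1L && any(diff(s$pos) <= 0))
      stop_invalid("positions must be sorted and unique within chromosome")
    grp <- cumsum(c(1, diff(s$pos) > merge_distance))
    data.frame(
      chrom = s$chrom[1L],
      start = tapply(s$pos, grp, min),
      end = tapply(s$pos, grp, max),
      n_sig_snps = as.integer(tapply(s$pos, grp, length)),
      max_logp = tapply(s$logp, grp, max),
      mean_logp = tapply(s$logp, grp, mean),
      member_positions = I(unname(split(s$pos, grp))))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_sig_snps = integer(),
                      max_logp = numeric(), mean_logp = numeric(),
                      member_positions = I(list()))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(island_id = if (nrow(out)) paste0("isl", seq_len(nrow(out)))
               else character(), out)
  rownames(out) <- NULL
  class(out) <- c("selection_islands", "data.frame")
  out
}

# gap between two 1-based inclusive intervals; 0 if they overlap
.interval_distance <- function(s1, e1, s2, e2) {
  ifelse(s2 > e1, s2 - e1, ifelse(s1 > e2, s1 - e2, 0))
}

.promoter_window <- function(genes, promoter_bp) {
  data.frame(
    start = ifelse(genes$strand == "+", genes$tss - promoter_bp,
                   genes$tss + 1),
    end = ifelse(genes$strand == "+", genes$tss - 1,
                 genes$tss + promoter_bp))
}

#' Link each selection island to its closest gene
#'
#' For each island, the gene on the same chromosome minimizing the
#' interval distance (0 for overlap) is chosen; distance ties are broken
#' by smaller gene start, then lexicographic `gene_id`, and the number of
#' tied genes is reported. The link is categorized as `gene_body` if the
#' island overlaps the gene body, else `promoter` if it overlaps the
#' strand-aware window `promoter_bp` upstream of the TSS, else
#' `intergenic`.
#'
#' @param islands a [merge_islands()] result (or data frame with
#'   `island_id`, `chrom`, `start`, `end`).
#' @param genes a gene annotation data frame (see
#'   [simulate_annotation()] / [read_annotation()]).
#' @param promoter_bp promoter window size upstream of the TSS (default
#'   5000).
#' @return A data frame with columns `island_id`, `gene_id`, `distance`,
#'   `category`, `n_ties`; islands on chromosomes without genes get an
#'   `NA` link.
#' @export
link_closest_gene <- function(islands, genes, promoter_bp = 5000) {
  genes <- as_gene_annotation(genes)
  check_scalar(promoter_bp, "promoter_bp", 1)
  prom <- .promoter_window(genes, promoter_bp)
  links <- lapply(seq_len(nrow(islands)), function(i) {
    isl <- islands[i, ]
    g <- genes[genes$chrom == isl$chrom, , drop = FALSE]
    pw <- prom[genes$chrom == isl$chrom, , drop = FALSE]
    if (nrow(g) == 0L)
      return(data.frame(island_id = isl$island_id, gene_id = NA_character_,
                        distance = NA_real_, category = NA_character_,
                        n_ties = 0L))
    d <- .interval_distance(isl$start, isl$end, g$start, g$end)
    ord <- order(d, g$start, g$gene_id)
    best <- ord[1L]
    category <- if (d[best] == 0) {
      "gene_body"
    } else if (.interval_distance(isl$start, isl$end, pw$start[best],
                                  pw$end[best]) == 0) {
      "promoter"
    } else {
      "intergenic"
    }
    data.frame(island_id = isl$island_id, gene_id = g$gene_id[best],
               distance = d[best], category = category,
               n_ties = as.integer(sum(d == d[best])))
  })
  out <- do.call(rbind, links)
  rownames(out) <- NULL
  out
}
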
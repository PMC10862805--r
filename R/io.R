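#' Write two haplotype panels as a phased VCF
#'
#' Consecutive pairs of haplotypes form diploid samples with phased GT
#' fields (`"a|b"`); REF/ALT are placeholder alleles. Population A
#' samples precede population B samples; a matching population map can be
#' written with [write_population_map()].
#'
#' @param pop_a,pop_b [haplotype_matrix()] panels over identical
#'   positions.
#' @param path output file (plain text).
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf_haplotypes <- function(pop_a, pop_b, path, seed = NULL) {
  assert_shared_positions(pop_a, pop_b)
  samp <- function(h) {
    n <- n_haplotypes(h)
    if (n %% 2 != 0) stop_invalid("panels must have an even number of haplotypes")
    sprintf("%s_%d", h$population_label, seq_len(n / 2))
  }
  samples <- c(samp(pop_a), samp(pop_b))
  al <- rbind(pop_a$alleles, pop_b$alleles)
  gt <- matrix(sprintf("%d|%d", al[seq(1, nrow(al), 2), ],
                       al[seq(2, nrow(al), 2), ]),
               nrow = nrow(al) / 2)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=crestscan_%s", as.character(packageVersion("crestscan"))),
    if (!is.null(seed)) sprintf("##crestscan_seed=%d", as.integer(seed)),
    sprintf("##contig=<ID=%s>", pop_a$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- cbind(pop_a$chrom, format(pop_a$positions, scientific = FALSE,
                                    trim = TRUE),
                ".", "A", "T", ".", "PASS", ".", "GT", t(gt))
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Write the two-column population map matching [write_vcf_haplotypes()]
#'
#' @param pop_a,pop_b the panels written to the VCF.
#' @param path output TSV (columns `sample_id`, `population`).
#' @return `path`, invisibly.
#' @export
write_population_map <- function(pop_a, pop_b, path) {
  map <- data.frame(
    sample_id = c(sprintf("%s_%d", pop_a$population_label,
                          seq_len(n_haplotypes(pop_a) / 2)),
                  sprintf("%s_%d", pop_b$population_label,
                          seq_len(n_haplotypes(pop_b) / 2))),
    population = rep(c(pop_a$population_label, pop_b$population_label),
                     c(n_haplotypes(pop_a) / 2, n_haplotypes(pop_b) / 2)))
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phased haplotype panels from a VCF
#'
#' Decodes phased GT fields into one haplotype matrix per population per
#' chromosome (two rows per diploid sample). Multi-allelic records and
#' records with any unphased or missing genotype are skipped and counted.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param population_map data frame with columns `sample_id` and
#'   `population`, or the path of such a TSV.
#' @return A list with one element per chromosome, each a list of
#'   [haplotype_matrix()] objects named by population; the number of
#'   skipped records is in attribute `"n_skipped"`.
#' @export
read_vcf_haplotypes <- function(path, population_map) {
  if (is.character(population_map))
    population_map <- read.table(population_map, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(population_map)))
    stop_invalid("population_map needs columns sample_id, population")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) stop_invalid("no usable records in VCF")
  missing <- setdiff(population_map$sample_id, colnames(gt))
  if (length(missing))
    stop_invalid("samples in map absent from VCF: ",
                 paste(missing, collapse = ", "))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ok_allelic <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  ok_gt <- apply(gt, 1, function(g) all(grepl("^[01]\\|[01]$", g)))
  keep <- ok_allelic & ok_gt
  n_skipped <- sum(!keep)
  if (!any(keep)) stop_invalid("no usable records in VCF")
  gt <- gt[keep, , drop = FALSE]
  chrom <- fix[keep, "CHROM"]
  pos <- as.numeric(fix[keep, "POS"])
  out <- lapply(split(seq_along(pos), chrom), function(idx) {
    idx <- idx[order(pos[idx])]
    pops <- lapply(split(population_map$sample_id,
                         population_map$population), function(ids) {
      h1 <- substr(gt[idx, ids, drop = FALSE], 1, 1)
      h2 <- substr(gt[idx, ids, drop = FALSE], 3, 3)
      al <- matrix(0L, 2L * length(ids), length(idx))
      al[seq(1, nrow(al), 2), ] <- t(matrix(as.integer(h1), length(idx)))
      al[seq(2, nrow(al), 2), ] <- t(matrix(as.integer(h2), length(idx)))
      al
    })
    lapply(setNames(names(pops), names(pops)), function(p) {
      haplotype_matrix(pops[[p]], pos[idx], chrom = chrom[idx][1L],
                       population = p)
    })
  })
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a gene annotation from BED6 or GFF3
#'
#' BED input is converted from 0-based half-open to the package's 1-based
#' inclusive coordinates; GFF3 coordinates are taken as 1-based, and only
#' `gene`-type features are kept. BED records without a usable strand or
#' with malformed coordinates are skipped with a warning carrying the
#' line number.
#'
#' @param path annotation file; format guessed from the extension unless
#'   `format` is given.
#' @param format `"bed"` or `"gff3"`.
#' @return A gene annotation data frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`).
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(gff3?|gtf)(\\.gz)?$", path,
                        ignore.case = TRUE)) "gff3" else "bed"
  g <- if (format == "bed") .read_bed6(path) else .read_gff3_genes(path)
  as_gene_annotation(g)
}

.read_bed6 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    start0 <- suppressWarnings(as.numeric(f[2]))
    end1 <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 6L || is.na(start0) || is.na(end1) ||
        !f[6] %in% c("+", "-")) {
      warning("skipping malformed BED record at line ", i, call. = FALSE)
      return(NULL)
    }
    data.frame(gene_id = f[4], chrom = f[1], start = start0 + 1,
               end = end1, strand = f[6], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_invalid("no usable BED records in ", path)
  out
}

.read_gff3_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_invalid("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) stop_invalid("no gene features in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  ok <- strand %in% c("+", "-")
  if (any(!ok))
    warning(sum(!ok), " gene feature(s) without strand skipped",
            call. = FALSE)
  gr <- gr[ok]
  id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation or island set as BED6
#'
#' Internal 1-based inclusive intervals are written as standard 0-based
#' half-open BED. For islands, the score column holds `n_sig_snps` and
#' the name column the island id.
#'
#' @param x a gene annotation or [merge_islands()] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  if (nrow(x) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (!is.null(x$gene_id)) {
    bed <- data.frame(x$chrom, format(x$start - 1, scientific = FALSE,
                                      trim = TRUE),
                      format(x$end, scientific = FALSE, trim = TRUE),
                      x$gene_id, 0L, x$strand)
  } else {
    bed <- data.frame(x$chrom, format(x$start - 1, scientific = FALSE,
                                      trim = TRUE),
                      format(x$end, scientific = FALSE, trim = TRUE),
                      x$island_id, x$n_sig_snps, ".")
  }
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a data frame as a commented TSV
#'
#' Metadata lines (parameters, seeds) are written as leading `#` comment
#' lines; missing values become `"."`.
#'
#' @param x data frame.
#' @param path output file.
#' @param comments character vector of metadata lines (without the `#`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comments = character()) {
  x <- as.data.frame(x)
  x[] <- lapply(x, function(col) {
    if (is.list(col)) col <- vapply(col, paste, character(1), collapse = ",")
    col[is.na(col)] <- "."
    col
  })
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV written by [write_tsv()]
#'
#' @param path input file.
#' @return A data frame; `"."` becomes `NA`.
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             na.strings = ".", stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()]; `scan`, `enrich`, `islands` and `expression`
#'   blocks are passed to their respective config constructors.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}
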
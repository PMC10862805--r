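#' Pipeline configuration
#'
#' Bundles inputs and stage parameters for [run_pipeline()]. Inputs can
#' be files (`vcf` + `population_map`, `genes_path`, `counts_path` +
#' `meta_path`) or, when a path is `NULL`, generated from the simulator
#' configurations in `sim`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed global seed recorded in the manifest and used to derive
#'   stage seeds.
#' @param vcf,population_map phased VCF and two-column population map
#'   (TSV), or `NULL` to simulate panels.
#' @param genes_path BED6/GFF3 gene annotation, or `NULL` to simulate.
#' @param counts_path,meta_path counts TSV (genes x samples, first column
#'   gene id) and sample metadata TSV, or `NULL` to simulate.
#' @param scan a [scan_config()].
#' @param logp_threshold,merge_distance,promoter_bp island-stage
#'   parameters.
#' @param k,lfc,alpha,min_count expression-stage parameters.
#' @param enrich an [enrich_config()].
#' @param sim list with optional elements `hap` ([hap_sim_config()]),
#'   `counts` ([counts_sim_config()]) and `annotation`
#'   ([annotation_sim_config()]) used for whichever inputs lack a path.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, vcf = NULL,
                            population_map = NULL, genes_path = NULL,
                            counts_path = NULL, meta_path = NULL,
                            scan = scan_config(), logp_threshold = 3,
                            merge_distance = 50000, promoter_bp = 5000,
                            k = 7, lfc = 0.585, alpha = 0.05,
                            min_count = 10, enrich = enrich_config(),
                            sim = list()) {
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(logp_threshold, "logp_threshold", 0)
  check_scalar(merge_distance, "merge_distance", 0)
  check_scalar(promoter_bp, "promoter_bp", 1)
  check_scalar(k, "k", 1, Inf, integer = TRUE)
  check_scalar(lfc, "lfc", 0)
  check_scalar(alpha, "alpha", 0, 1)
  check_scalar(min_count, "min_count", 0)
  if (is.list(scan) && !inherits(scan, "scan_config"))
    scan <- do.call(scan_config, scan)
  if (is.list(enrich) && !inherits(enrich, "enrich_config"))
    enrich <- do.call(enrich_config, enrich)
  for (p in c(vcf, population_map, genes_path, counts_path, meta_path))
    if (!file.exists(p)) stop_invalid("input file not found: ", p)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), vcf = vcf,
         population_map = population_map, genes_path = genes_path,
         counts_path = counts_path, meta_path = meta_path, scan = scan,
         logp_threshold = logp_threshold, merge_distance = merge_distance,
         promoter_bp = promoter_bp, k = as.integer(k), lfc = lfc,
         alpha = alpha, min_count = min_count, enrich = enrich,
         sim = sim),
    class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_invalid("[stage ", name, "] ", conditionMessage(e))
  })
}

#' Run the full scan-to-enrichment pipeline
#'
#' Executes scan, island construction and gene linking, expression
#' normalization, DEG calling, profile clustering, and per-cluster
#' enrichment; writes every table to `cfg$out_dir` (scan.tsv,
#' islands.bed, island_gene_links.tsv, deg.tsv, clusters.tsv,
#' cluster_centroids.tsv, enrichment.tsv) plus a machine-readable
#' `manifest.json` with package version, seeds, parameters and input
#' checksums. Two runs with the same configuration and seed produce
#' byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config"))
    stop_invalid("cfg must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "crestscan",
    version = as.character(packageVersion("crestscan")),
    seed = cfg$seed,
    parameters = list(
      scan = unclass(cfg$scan), logp_threshold = cfg$logp_threshold,
      merge_distance = cfg$merge_distance, promoter_bp = cfg$promoter_bp,
      k = cfg$k, lfc = cfg$lfc, alpha = cfg$alpha,
      min_count = cfg$min_count, enrich = unclass(cfg$enrich)),
    inputs = list(), counts_log = list(), outputs = character())

  # --- inputs -------------------------------------------------------------
  panels <- .stage("input_haplotypes", {
    if (!is.null(cfg$vcf)) {
      manifest$inputs$vcf <- unname(tools::md5sum(cfg$vcf))
      chroms <- read_vcf_haplotypes(cfg$vcf, cfg$population_map)
      manifest$counts_log$vcf_records_skipped <- attr(chroms, "n_skipped")
      lapply(chroms, function(ch) {
        pops <- names(ch)
        list(pop_a = ch[[pops[1L]]], pop_b = ch[[pops[2L]]])
      })
    } else {
      hap <- cfg$sim$hap
      if (is.null(hap)) hap <- hap_sim_config(seed = cfg$seed)
      list(simulate_haplotypes(hap))
    }
  })
  genes <- .stage("input_annotation", {
    if (!is.null(cfg$genes_path)) {
      manifest$inputs$genes <- unname(tools::md5sum(cfg$genes_path))
      read_annotation(cfg$genes_path)
    } else {
      ann <- cfg$sim$annotation
      if (is.null(ann)) ann <- annotation_sim_config(seed = cfg$seed + 1L)
      simulate_annotation(ann)
    }
  })
  expr_in <- .stage("input_counts", {
    if (!is.null(cfg$counts_path)) {
      manifest$inputs$counts <- unname(tools::md5sum(cfg$counts_path))
      manifest$inputs$meta <- unname(tools::md5sum(cfg$meta_path))
      cts <- read_tsv(cfg$counts_path)
      counts <- as.matrix(cts[, -1, drop = FALSE])
      rownames(counts) <- cts[[1L]]
      list(counts = counts, meta = read_tsv(cfg$meta_path))
    } else {
      csim <- cfg$sim$counts
      if (is.null(csim)) csim <- counts_sim_config(seed = cfg$seed + 2L)
      simulate_counts(csim)
    }
  })

  # --- scan ---------------------------------------------------------------
  records <- .stage("scan", xpehh_scan_multi(panels, cfg$scan))
  write_tsv(records, file.path(cfg$out_dir, "scan.tsv"),
            comments = c(sprintf("crestscan scan, seed %d", cfg$seed),
                         "xpehh_raw = ln(iES_A / iES_B): positive values mean longer haplotypes in population A"))

  # --- islands ------------------------------------------------------------
  sig <- .stage("islands", significant_sites(records, cfg$logp_threshold))
  islands <- .stage("islands", merge_islands(sig, cfg$merge_distance))
  links <- .stage("islands", {
    if (nrow(islands)) link_closest_gene(islands, genes, cfg$promoter_bp)
    else data.frame(island_id = character(), gene_id = character(),
                    distance = numeric(), category = character(),
                    n_ties = integer())
  })
  write_bed6(islands, file.path(cfg$out_dir, "islands.bed"))
  write_tsv(links, file.path(cfg$out_dir, "island_gene_links.tsv"))
  manifest$counts_log$n_significant_snps <- nrow(sig)
  manifest$counts_log$n_islands <- nrow(islands)

  # --- expression ---------------------------------------------------------
  expr <- .stage("expression", {
    counts <- expr_in$counts
    meta <- expr_in$meta
    keep <- low_count_filter(counts, meta, cfg$min_count)
    counts <- counts[keep, , drop = FALSE]
    factors <- size_factors(counts)
    contrasts <- species_stage_contrasts(meta)
    de <- do.call(rbind, lapply(contrasts, function(ct)
      de_contrast(counts, factors, meta, ct)))
    degs <- call_degs(de, cfg$lfc, cfg$alpha)
    profiles <- stage_profiles(counts, factors, meta, degs$deg_genes)
    clusters <- if (sum(!profiles$excluded) >= cfg$k)
      cluster_profiles(profiles, cfg$k) else NULL
    list(retained = keep, factors = factors, de = degs$records,
         deg_genes = degs$deg_genes, profiles = profiles,
         clusters = clusters)
  })
  write_tsv(expr$de, file.path(cfg$out_dir, "deg.tsv"))
  if (!is.null(expr$clusters)) {
    write_tsv(data.frame(gene_id = names(expr$clusters$assignment),
                         cluster_id = unname(expr$clusters$assignment)),
              file.path(cfg$out_dir, "clusters.tsv"))
    write_tsv(data.frame(cluster_id = rownames(expr$clusters$centroids),
                         expr$clusters$centroids, check.names = FALSE),
              file.path(cfg$out_dir, "cluster_centroids.tsv"))
  }
  manifest$counts_log$n_genes_low_count_removed <-
    nrow(expr_in$counts) - length(expr$retained)
  manifest$counts_log$n_degs <- length(expr$deg_genes)

  # --- enrichment ---------------------------------------------------------
  enrichment <- .stage("enrichment", {
    if (is.null(expr$clusters)) return(NULL)
    # expression gene ids and annotation ids come from different sources
    # in simulated runs; map cluster labels onto annotated genes by rank
    assignment <- expr$clusters$assignment
    if (!any(names(assignment) %in% genes$gene_id)) {
      n <- min(length(assignment), nrow(genes))
      assignment <- setNames(assignment[seq_len(n)],
                             genes$gene_id[seq_len(n)])
    }
    enrichment_by_cluster(assignment, genes, records, cfg$enrich)
  })
  if (!is.null(enrichment))
    write_tsv(enrichment, file.path(cfg$out_dir, "enrichment.tsv"))

  manifest$outputs <- list.files(cfg$out_dir)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(records = records, islands = islands, links = links,
                 expression = expr, enrichment = enrichment,
                 manifest = manifest))
}
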
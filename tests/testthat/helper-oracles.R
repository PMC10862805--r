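# Independent reference implementations used to check the package's
# computations. These deliberately use direct enumeration rather than the
# package's algorithms.

# random haplotype panel with intermediate-frequency sites
random_panel <- function(n_hap, n_sites, span = n_sites * 200,
                         population = "pop") {
  positions <- sort(sample.int(span, n_sites))
  f <- runif(n_sites, 0.15, 0.85)
  al <- matrix(rbinom(n_hap * n_sites, 1L, rep(f, each = n_hap)),
               n_hap, n_sites)
  haplotype_matrix(al, positions, population = population)
}

# EHHS by explicit enumeration of homozygous pairs: for every site x on one
# side of the focal, count haplotype pairs identical over the closed
# interval [focal, x]
oracle_ehhs_side <- function(al, focal, dir) {
  n <- nrow(al)
  L <- ncol(al)
  idx <- if (dir > 0) seq(focal, L) else seq(focal, 1)
  pairs <- utils::combn(n, 2)
  ident <- rep(TRUE, ncol(pairs))
  vals <- numeric(0)
  h0 <- NA_real_
  for (step in seq_along(idx)) {
    j <- idx[step]
    ident <- ident & (al[pairs[1, ], j] == al[pairs[2, ], j])
    h <- sum(ident) / ncol(pairs)
    if (step == 1) h0 <- h else vals <- c(vals, h / h0)
  }
  c(1, vals)
}

# transitive closure of "within d" on sorted positions, by repeated O(n^2)
# expansion of island membership
oracle_merge <- function(pos, d) {
  stopifnot(!is.unsorted(pos, strictly = TRUE))
  grp <- seq_along(pos)
  repeat {
    changed <- FALSE
    for (i in seq_along(pos)) {
      near <- abs(pos - pos[i]) <= d
      g <- min(grp[near])
      if (any(grp[near] != g)) {
        grp[near] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(pos, grp), range))
}

# exhaustive closest-gene search: distance of an interval to every gene
oracle_closest <- function(start, end, genes) {
  d <- vapply(seq_len(nrow(genes)), function(i) {
    if (genes$start[i] > end) genes$start[i] - end
    else if (start > genes$end[i]) start - genes$end[i]
    else 0
  }, numeric(1))
  ord <- order(d, genes$start, genes$gene_id)
  list(gene_id = genes$gene_id[ord[1]], distance = d[ord[1]])
}

# small standard expression fixture: simulated counts plus derived objects
make_counts_fixture <- function(seed = 42, n_genes = 120) {
  sim <- simulate_counts(counts_sim_config(n_genes = n_genes, seed = seed))
  keep <- low_count_filter(sim$counts, sim$meta)
  counts <- sim$counts[keep, , drop = FALSE]
  factors <- size_factors(counts)
  list(sim = sim, counts = counts, factors = factors, meta = sim$meta)
}
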
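#' Configuration for the two-population haplotype simulator
#'
#' Parameters of a forward Wright-Fisher simulation of binary haplotypes for
#' two populations that share a founding panel and then evolve
#' independently, optionally with a hard selective sweep in population A.
#' The simulator is a controllable stand-in for a pair of diverging wild
#' populations, not a demographic model of any particular lake or species:
#' its purpose is to provide phased panels with known ground truth
#' (neutrality, or a sweep at a known position) for validating the scan.
#'
#' A population of `pop_size` haplotypes evolves for `n_generations`
#' generations with uniform crossover at `recombination_rate` per bp per
#' generation; `n_haplotypes_per_pop` haplotypes are then sampled as the
#' panel. Keeping `pop_size` well above the panel size makes most sampled
#' pairs coalesce beyond the founding panel, so neutral haplotype
#' homozygosity decays over a few kb while swept haplotypes, which share a
#' common ancestor only `sweep_time` generations back, stay homozygous over
#' tens of kb -- the contrast the cross-population statistic detects.
#'
#' Sites are biallelic under an infinite-sites approximation (no
#' back-mutation): a fraction `founding_fraction` of the `n_sites` sites
#' segregates in the founding panel (founding frequencies drawn uniformly
#' on \[0.1, 0.9\], emulating shared standing variation), and the rest enter
#' as population-private single-copy mutations in a uniformly drawn
#' generation.
#'
#' If `sweep_position` is set and `selection_coefficient > 0`, the
#' segregating site nearest `sweep_position` becomes the sweep locus: it is
#' re-initialized to a single derived copy arising in population A
#' `sweep_time` generations before sampling, and carriers have
#' multiplicative fitness `1 + s` in population A only. If the allele is
#' lost, population A's evolution is re-run (conditioning on establishment;
#' this only happens under selection, so `s = 0` reduces bit-identically to
#' the neutral model under the same seed).
#'
#' @param n_haplotypes_per_pop sampled panel size per population; positive
#'   even integer (two haplotypes per diploid).
#' @param chrom_length chromosome length in bp.
#' @param mutation_density expected segregating sites per bp; sets the
#'   default `n_sites = round(mutation_density * chrom_length)`.
#' @param n_sites number of segregating sites (overrides
#'   `mutation_density`).
#' @param recombination_rate per-bp per-generation crossover probability.
#' @param n_generations generations of forward evolution after the split.
#' @param sweep_position bp position of the selected locus, or `NULL` for
#'   neutral evolution.
#' @param selection_coefficient s >= 0; multiplicative fitness advantage
#'   `1 + s` of derived-allele carriers at the sweep locus in population A.
#' @param sweep_time generations before sampling at which the beneficial
#'   allele arises (capped at `n_generations`).
#' @param pop_size number of haplotypes in each evolving population.
#' @param founding_fraction fraction of sites segregating in the founding
#'   panel; the remainder arise as new mutations during the simulation.
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical output.
#' @param chrom chromosome name used in the output panels.
#'
#' @return An object of class `hap_sim_config`.
#' @seealso [simulate_haplotypes()]
#' @export
hap_sim_config <- function(n_haplotypes_per_pop = 60L, chrom_length = 1e6,
                           mutation_density = 0.01, n_sites = NULL,
                           recombination_rate = 1e-6, n_generations = 60L,
                           sweep_position = NULL, selection_coefficient = 0,
                           sweep_time = 45L, pop_size = 1000L,
                           founding_fraction = 0.85, seed = 1L,
                           chrom = "chr1") {
  check_scalar(n_haplotypes_per_pop, "n_haplotypes_per_pop", 2, Inf,
               integer = TRUE)
  if (n_haplotypes_per_pop %% 2 != 0)
    stop_invalid("n_haplotypes_per_pop must be even (two haplotypes per diploid)")
  check_scalar(chrom_length, "chrom_length", 2)
  check_scalar(mutation_density, "mutation_density", 1e-12, 1)
  if (is.null(n_sites)) n_sites <- round(mutation_density * chrom_length)
  check_scalar(n_sites, "n_sites", 2, chrom_length, integer = TRUE)
  check_scalar(recombination_rate, "recombination_rate", 0, 1)
  check_scalar(n_generations, "n_generations", 1, Inf, integer = TRUE)
  if (!is.null(sweep_position)) {
    check_scalar(sweep_position, "sweep_position")
    if (sweep_position < 1 || sweep_position > chrom_length)
      stop_invalid("sweep_position must lie in [1, chrom_length]")
  }
  check_scalar(selection_coefficient, "selection_coefficient", 0)
  check_scalar(sweep_time, "sweep_time", 1, Inf, integer = TRUE)
  check_scalar(pop_size, "pop_size", n_haplotypes_per_pop, Inf, integer = TRUE)
  check_scalar(founding_fraction, "founding_fraction", 0, 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(n_haplotypes_per_pop = as.integer(n_haplotypes_per_pop),
         chrom_length = chrom_length, mutation_density = mutation_density,
         n_sites = as.integer(n_sites),
         recombination_rate = recombination_rate,
         n_generations = as.integer(n_generations),
         sweep_position = sweep_position,
         selection_coefficient = selection_coefficient,
         sweep_time = as.integer(sweep_time),
         pop_size = as.integer(pop_size),
         founding_fraction = founding_fraction,
         seed = as.integer(seed), chrom = as.character(chrom)),
    class = "hap_sim_config")
}

#' Simulate two phased haplotype panels, neutral or with a hard sweep
#'
#' Forward Wright-Fisher simulation of two populations from a shared
#' founding panel; see [hap_sim_config()] for the model. Population A
#' carries the sweep (if any); population B always evolves neutrally.
#'
#' @param cfg a [hap_sim_config()].
#' @return A list with elements `pop_a` and `pop_b` (each a
#'   [haplotype_matrix()] over identical positions), `sweep_site` (bp
#'   position of the realized sweep locus, or `NULL`) and
#'   `sweep_frequency` (derived-allele frequency at that locus in the
#'   sampled population-A panel, or `NULL`).
#' @export
#' @examples
#' sim <- simulate_haplotypes(hap_sim_config(
#'   n_haplotypes_per_pop = 20, chrom_length = 1e5, n_sites = 200,
#'   pop_size = 60, n_generations = 30, seed = 7))
#' sim$pop_a
simulate_haplotypes <- function(cfg) {
  if (!inherits(cfg, "hap_sim_config"))
    stop_invalid("cfg must be a hap_sim_config")
  set.seed(cfg$seed)
  n <- cfg$pop_size
  L <- cfg$n_sites
  G <- cfg$n_generations

  positions <- sort(sample.int(cfg$chrom_length, L))
  founding <- runif(L) < cfg$founding_fraction
  nf <- sum(founding)
  panel <- matrix(0L, n, L)
  if (nf > 0L) {
    f <- runif(nf, 0.1, 0.9)
    panel[, founding] <- matrix(rbinom(n * nf, 1L, rep(f, each = n)), n, nf)
  }

  # population-private new mutations at the non-founding sites
  new_sites <- which(!founding)
  ev <- data.frame(
    site = new_sites,
    pop = sample(c("A", "B"), length(new_sites), replace = TRUE),
    gen = sample.int(G, length(new_sites), replace = TRUE),
    hap = sample.int(n, length(new_sites), replace = TRUE))

  sweep_locus <- NULL
  if (!is.null(cfg$sweep_position)) {
    sweep_locus <- which.min(abs(positions - cfg$sweep_position))
    if (cfg$selection_coefficient > 0) {
      # hard sweep: single-origin derived allele arising sweep_time
      # generations before sampling, in population A only
      panel[, sweep_locus] <- 0L
      ev <- ev[ev$site != sweep_locus, , drop = FALSE]
      origin_gen <- max(1L, G - cfg$sweep_time)
      ev <- rbind(ev, data.frame(site = sweep_locus, pop = "A",
                                 gen = origin_gen,
                                 hap = sample.int(n, 1L)))
    }
  }

  evolve <- function(pop_label, s_eff) {
    evs <- ev[ev$pop == pop_label, , drop = FALSE]
    emat <- cbind(evs$gen, evs$hap - 1L, evs$site - 1L)
    storage.mode(emat) <- "integer"
    sweep0 <- if (is.null(sweep_locus)) -1L else sweep_locus - 1L
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      p <- wf_evolve_cpp(panel, positions, cfg$chrom_length,
                         cfg$recombination_rate, G, s_eff, sweep0, emat)
      established <- s_eff <= 0 || is.null(sweep_locus) ||
        sum(p[, sweep_locus]) > 0L
      if (established || attempt >= 50L) break
    }
    p
  }

  s_a <- if (is.null(sweep_locus)) 0 else cfg$selection_coefficient
  pop_a_full <- evolve("A", s_a)
  pop_b_full <- evolve("B", 0)

  take_a <- sample.int(n, cfg$n_haplotypes_per_pop)
  take_b <- sample.int(n, cfg$n_haplotypes_per_pop)
  pa <- pop_a_full[take_a, , drop = FALSE]
  pb <- pop_b_full[take_b, , drop = FALSE]

  list(
    pop_a = haplotype_matrix(pa, positions, chrom = cfg$chrom,
                             population = "A"),
    pop_b = haplotype_matrix(pb, positions, chrom = cfg$chrom,
                             population = "B"),
    sweep_site = if (is.null(sweep_locus)) NULL else positions[sweep_locus],
    sweep_frequency = if (is.null(sweep_locus)) NULL else
      mean(pa[, sweep_locus]))
}
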
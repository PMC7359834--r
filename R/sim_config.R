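#' Configuration for the two-deme Wright-Fisher simulator
#'
#' Parameterizes a forward simulation of two diploid demes (an affected
#' and a control population) exchanging migrants, with viability
#' selection at a single multi-allelic candidate locus that can be
#' switched off at an intervention generation, and unlinked neutral
#' microsatellites evolving under a stepwise mutation model.
#'
#' Migration is backward (destination-based): `migration[i, j]` is the
#' probability that the parents of an offspring born in deme `i` are
#' drawn from deme `j`, so rows must sum to 1. Generations are discrete
#' and non-overlapping (the study species has a 1-year generation time,
#' so one generation = one year). The cohort produced in generation `t`
#' experiences the `"before"` fitness map iff `t <= switch_generation`,
#' and the `"after"` map otherwise.
#'
#' @param deme_sizes Integer vector of length 2: diploid individuals per
#'   deme (constant across generations).
#' @param deme_names Labels for the two demes, used as site labels in the
#'   emitted samples. Default `c("MEL", "SFM")` (affected, control).
#' @param migration 2x2 backward migration matrix; rows sum to 1.
#' @param candidate_alleles Character vector of candidate-locus allele
#'   labels (e.g. 5-bp haplotypes).
#' @param candidate_init_freqs 2 x K matrix (rows = demes) of initial
#'   allele frequencies at the candidate locus; each row sums to 1.
#' @param fitness_by_epoch Nested list `[[deme name]][[epoch]]` of named
#'   relative viabilities (>= 0). Names are either genotype categories
#'   (`focal_homozygote`, `focal_heterozygote`, `other_homozygote`,
#'   `other_heterozygote`; requires `focal_allele`) or explicit unordered
#'   allele pairs `"A/B"`. Unnamed genotypes default to viability 1;
#'   missing demes/epochs are fully neutral.
#' @param focal_allele Label of the focal candidate allele (needed when
#'   `fitness_by_epoch` uses category names).
#' @param n_microsats Number of microsatellite loci.
#' @param microsat_init List (length `n_microsats`) of lists with integer
#'   `alleles` (repeat numbers) and `freqs`; recycled if length 1.
#'   Monomorphic loci are allowed (single allele).
#' @param mu_stepwise Per-locus per-generation stepwise mutation rate in
#'   `[0, 1)`; mutation adds or subtracts one repeat (direction uniform),
#'   reflecting at `microsat_floor`.
#' @param microsat_floor Smallest permitted repeat number (default 1).
#' @param n_generations Number of generations to simulate.
#' @param switch_generation Generation at which the epoch flips from
#'   `"before"` to `"after"`.
#' @param sampling_plan Data frame with columns `generation` (0 =
#'   initial state), `deme` (index or name), `size`, and optionally
#'   `year` (defaults to `generation`).
#' @param seed Integer seed; all stochastic draws flow from it.
#'
#' @return A validated object of class `simulation_config`.
#' @seealso [simulate_two_deme()], [deterministic_trajectory()],
#'   [study_config()]
#' @export
simulation_config <- function(deme_sizes,
                              migration,
                              candidate_alleles,
                              candidate_init_freqs,
                              fitness_by_epoch = list(),
                              focal_allele = NULL,
                              n_microsats = 0L,
                              microsat_init = list(),
                              mu_stepwise = 0,
                              microsat_floor = 1L,
                              n_generations = 1L,
                              switch_generation = n_generations,
                              sampling_plan = NULL,
                              deme_names = c("MEL", "SFM"),
                              seed = 1L) {
  deme_sizes <- as.integer(deme_sizes)
  if (length(deme_sizes) != 2L || any(deme_sizes < 1L))
    stop("deme_sizes must be two positive integers")
  migration <- as.matrix(migration)
  if (!identical(dim(migration), c(2L, 2L)) || any(migration < 0))
    stop("migration must be a non-negative 2x2 matrix")
  if (any(abs(rowSums(migration) - 1) > 1e-12))
    stop("migration rows must sum to 1 (within 1e-12)")
  candidate_alleles <- as.character(candidate_alleles)
  K <- length(candidate_alleles)
  if (K < 1L || anyDuplicated(candidate_alleles))
    stop("candidate_alleles must be distinct, non-empty labels")
  candidate_init_freqs <- matrix(as.numeric(candidate_init_freqs), nrow = 2L)
  if (ncol(candidate_init_freqs) != K)
    stop("candidate_init_freqs must be a 2 x n_alleles matrix")
  if (any(candidate_init_freqs < 0) ||
      any(abs(rowSums(candidate_init_freqs) - 1) > 1e-9))
    stop("each row of candidate_init_freqs must sum to 1 (within 1e-9)")
  if (!is.null(focal_allele) && !focal_allele %in% candidate_alleles)
    stop("focal_allele must be one of candidate_alleles")
  n_microsats <- as.integer(n_microsats)
  if (n_microsats > 0L) {
    if (length(microsat_init) == 1L)
      microsat_init <- rep(microsat_init, n_microsats)
    if (length(microsat_init) != n_microsats)
      stop("microsat_init must supply one entry per microsatellite locus")
    for (m in microsat_init) {
      if (any(m$alleles < 1) || any(m$alleles != round(m$alleles)))
        stop("microsatellite alleles must be positive integers")
      if (length(m$alleles) != length(m$freqs) ||
          any(m$freqs < 0) || abs(sum(m$freqs) - 1) > 1e-9)
        stop("microsatellite initial frequencies must match alleles and sum to 1")
    }
  }
  if (mu_stepwise < 0 || mu_stepwise >= 1)
    stop("mu_stepwise must be in [0, 1)")
  n_generations <- as.integer(n_generations)
  switch_generation <- as.integer(switch_generation)
  if (n_generations < 1L) stop("n_generations must be positive")
  if (switch_generation > n_generations)
    stop("switch_generation must be <= n_generations")
  if (is.null(sampling_plan))
    sampling_plan <- data.frame(generation = integer(), deme = integer(),
                                size = integer(), year = integer())
  sampling_plan <- as.data.frame(sampling_plan)
  if (nrow(sampling_plan)) {
    if (is.character(sampling_plan$deme))
      sampling_plan$deme <- match(sampling_plan$deme, deme_names)
    if (anyNA(sampling_plan$deme) || any(!sampling_plan$deme %in% 1:2))
      stop("sampling_plan demes must name one of the two demes")
    if (!"year" %in% names(sampling_plan))
      sampling_plan$year <- sampling_plan$generation
    if (any(sampling_plan$generation < 0L) ||
        any(sampling_plan$generation > n_generations))
      stop("sampling_plan generations must lie in [0, n_generations]")
    over <- sampling_plan$size > deme_sizes[sampling_plan$deme]
    if (any(over))
      stop(sprintf("sampling_plan requests %d individuals from deme %d of size %d",
                   sampling_plan$size[over][1L],
                   sampling_plan$deme[over][1L],
                   deme_sizes[sampling_plan$deme[over][1L]]))
  }
  cfg <- structure(
    list(deme_sizes = deme_sizes, deme_names = deme_names,
         migration = migration,
         candidate_alleles = candidate_alleles,
         candidate_init_freqs = candidate_init_freqs,
         fitness_by_epoch = fitness_by_epoch, focal_allele = focal_allele,
         n_microsats = n_microsats, microsat_init = microsat_init,
         mu_stepwise = mu_stepwise, microsat_floor = as.integer(microsat_floor),
         n_generations = n_generations,
         switch_generation = switch_generation,
         sampling_plan = sampling_plan, seed = as.integer(seed)),
    class = "simulation_config")
  # at least one positive viability per deme and epoch
  for (d in 1:2) for (ep in c("before", "after")) {
    V <- viability_matrix(cfg, d, ep)
    if (all(V <= 0))
      stop(sprintf("all viabilities are zero for deme %s, epoch %s",
                   deme_names[d], ep))
  }
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: demes %s (%s), %d generations, switch at %d\n",
              paste(x$deme_sizes, collapse = "/"),
              paste(x$deme_names, collapse = "/"),
              x$n_generations, x$switch_generation))
  cat(sprintf("  candidate: %d alleles; microsats: %d (mu = %g); seed %d\n",
              length(x$candidate_alleles), x$n_microsats, x$mu_stepwise,
              x$seed))
  cat(sprintf("  sampling plan: %d entries\n", nrow(x$sampling_plan)))
  invisible(x)
}

# K x K viability matrix for a deme (index) and epoch, from the fitness map.
# Pair keys "A/B" win over category names; unspecified genotypes get 1.
viability_matrix <- function(config, deme, epoch) {
  K <- length(config$candidate_alleles)
  V <- matrix(1, K, K)
  fm <- config$fitness_by_epoch
  entry <- NULL
  if (!is.null(fm)) {
    dn <- config$deme_names[deme]
    entry <- fm[[dn]][[epoch]]
    if (is.null(entry)) entry <- fm[[as.character(deme)]][[epoch]]
  }
  if (is.null(entry) || !length(entry)) return(V)
  if (any(entry < 0)) stop("viabilities must be >= 0")
  nm <- names(entry)
  if (is.null(nm)) stop("fitness map entries must be named")
  cats <- c("focal_homozygote", "focal_heterozygote",
            "other_homozygote", "other_heterozygote")
  for (i in seq_along(entry)) {
    key <- nm[i]
    w <- as.numeric(entry[i])
    if (grepl("/", key, fixed = TRUE)) {
      ab <- strsplit(key, "/", fixed = TRUE)[[1L]]
      u <- match(ab[1L], config$candidate_alleles)
      v <- match(ab[2L], config$candidate_alleles)
      if (is.na(u) || is.na(v))
        stop(sprintf("fitness key '%s' names an unknown allele", key))
      V[u, v] <- w; V[v, u] <- w
    } else if (key %in% cats) {
      if (is.null(config$focal_allele))
        stop("category fitness keys require focal_allele in the config")
      f <- match(config$focal_allele, config$candidate_alleles)
      idx <- switch(key,
        focal_homozygote = cbind(f, f),
        focal_heterozygote = {
          o <- setdiff(seq_len(K), f)
          rbind(cbind(f, o), cbind(o, f))
        },
        other_homozygote = {
          o <- setdiff(seq_len(K), f)
          cbind(o, o)
        },
        other_heterozygote = {
          o <- setdiff(seq_len(K), f)
          g <- expand.grid(o, o)
          as.matrix(g[g[, 1L] != g[, 2L], , drop = FALSE])
        })
      V[idx] <- w
    } else {
      stop(sprintf("unrecognized fitness key '%s'", key))
    }
  }
  V
}

epoch_of <- function(config, generation) {
  if (generation <= config$switch_generation) "before" else "after"
}
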
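#' Study-like default simulation scenario
#'
#' A ready-made [simulation_config()] emulating the structure of the
#' silverside monitoring study: an affected (MEL) and a control (SFM)
#' deme exchanging ~15% of recruits per generation, two samples of 24
#' individuals before and two after an epoch switch, a six-allele
#' candidate locus whose focal homozygote has relative viability
#' `1 - s` in the affected deme before the switch and is neutral
#' afterwards, and eight microsatellites (six polymorphic, two
#' monomorphic) under stepwise mutation.
#'
#' Deme sizes, initial frequencies and the placement of the sampling
#' generations are free parameters of the study system (census sizes
#' are unknown); the defaults were fixed by a design-time power
#' analysis documented in the methods vignette. The two before samples
#' are taken at generations 0 and 1 and the switch sits at generation
#' 10 (after samples at 11 and 12): because viability selection here
#' operates throughout the before epoch, widely spaced before samples
#' would themselves straddle most of the allele-frequency decline,
#' which the real study's stable pre-intervention frequencies did not
#' show. An affected-deme focal frequency of 0.60 keeps the pooled
#' non-focal category common enough that before-frequencies are
#' essentially never zero in samples of 24, while leaving a large
#' before/after contrast at s = 0.5.
#'
#' @param seed Integer seed.
#' @param s Selection coefficient against the focal homozygote in the
#'   affected deme before the switch (viability `1 - s`).
#' @param migration_rate Off-diagonal backward migration rate (both
#'   directions).
#' @param deme_size Diploid individuals per deme.
#' @param sample_size Individuals per sample.
#' @return A [simulation_config()].
#' @export
study_config <- function(seed = 1L, s = 0.5, migration_rate = 0.15,
                         deme_size = 5000L, sample_size = 24L) {
  alleles <- c("GTCGC", "CTCGC", "GTCGA", "CTCGA", "GTTGC", "CTTGC")
  other <- c(0.25, 0.20, 0.12, 0.08, 0.05)
  init <- rbind(
    MEL = c(0.60, 0.40 * other / sum(other)),
    SFM = c(0.25, 0.75 * other / sum(other)))
  msat_poly <- lapply(1:6, function(i) {
    fr <- c(0.30, 0.25, 0.20, 0.15, 0.10)
    # rotate so the loci differ without extra parameters
    list(alleles = seq(8L + i, by = 2L, length.out = 5L),
         freqs = fr[((seq_len(5) + i) %% 5) + 1L])
  })
  msat_mono <- list(list(alleles = 12L, freqs = 1),
                    list(alleles = 15L, freqs = 1))
  plan <- expand.grid(generation = c(0L, 1L, 11L, 12L), deme = 1:2)
  plan$size <- sample_size
  plan$year <- 2007L + plan$generation
  simulation_config(
    deme_sizes = c(deme_size, deme_size),
    migration = matrix(c(1 - migration_rate, migration_rate,
                         migration_rate, 1 - migration_rate),
                       2L, 2L, byrow = TRUE),
    candidate_alleles = alleles,
    candidate_init_freqs = init,
    fitness_by_epoch = list(
      MEL = list(before = c(focal_homozygote = 1 - s))),
    focal_allele = "GTCGC",
    n_microsats = 8L,
    microsat_init = c(msat_poly, msat_mono),
    mu_stepwise = 5e-4,
    n_generations = 12L,
    switch_generation = 10L,
    sampling_plan = plan,
    deme_names = c("MEL", "SFM"),
    seed = seed)
}

#' Study-like default expression generator configuration
#'
#' True per-million means chosen so that the affected/control expression
#' ratio is 18.7 before and 3.37 after the intervention, with the
#' published library-size ranges per sequencing campaign.
#'
#' @param seed Integer seed.
#' @param n_before,n_after Individuals per site in each epoch.
#' @return An [expression_config()].
#' @export
study_expression_config <- function(seed = 1L, n_before = 3L, n_after = 6L) {
  expression_config(
    mu = matrix(c(18.7 * 5, 5, 3.37 * 5, 5), 2L, 2L),
    dispersion = 0.3,
    n_individuals = matrix(c(n_before, n_before, n_after, n_after), 2L, 2L),
    seed = seed)
}

#' Study-like default water-chemistry generator configuration
#'
#' The affected site's pre-remediation means are elevated in the
#' salinity/ion block (EC, TDS, Na, K, Ca, Mg, NO3, NH4) and depressed
#' in dissolved oxygen; after remediation they return to control-site
#' levels, which are identical in both epochs.
#'
#' @param seed Integer seed.
#' @param replicates Replicates per site x year.
#' @return A [water_config()].
#' @export
study_water_config <- function(seed = 1L, replicates = 4L) {
  clean <- c(EC = 700, pH = 7.9, TDS = 450, NO3 = 3, NH4 = 0.4,
             Na = 60, K = 5, Ca = 80, Mg = 20, DO = 8.5)
  polluted <- c(EC = 1250, pH = 7.6, TDS = 820, NO3 = 8, NH4 = 2.5,
                Na = 180, K = 12, Ca = 150, Mg = 42, DO = 4.5)
  sds <- 0.12 * (clean + polluted) / 2
  water_config(
    means = list(MEL = list(before = polluted, after = clean),
                 SFM = list(before = clean, after = clean)),
    covariance = diag(sds^2),
    replicates = replicates,
    seed = seed)
}
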
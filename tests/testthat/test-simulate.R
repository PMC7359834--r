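neutral_cfg <- function(deme = 200L, gens = 4L, seed = 1L, migration = 0.15,
                        plan = NULL, n_msat = 0L, ...) {
  simulation_config(
    deme_sizes = c(deme, deme),
    migration = matrix(c(1 - migration, migration,
                         migration, 1 - migration), 2, 2, byrow = TRUE),
    candidate_alleles = c("A", "B"),
    candidate_init_freqs = rbind(c(0.5, 0.5), c(0.5, 0.5)),
    n_generations = gens, switch_generation = gens,
    n_microsats = n_msat,
    microsat_init = if (n_msat > 0)
      list(list(alleles = c(10L, 12L, 14L), freqs = c(0.5, 0.3, 0.2))),
    sampling_plan = plan, seed = seed, ...)
}

test_that("identical config and seed give byte-identical samples", {
  plan <- data.frame(generation = c(2L, 4L), deme = c(1L, 2L), size = 20L)
  s1 <- simulate_two_deme(neutral_cfg(plan = plan, n_msat = 2L,
                                      mu_stepwise = 1e-3, seed = 99L))
  s2 <- simulate_two_deme(neutral_cfg(plan = plan, n_msat = 2L,
                                      mu_stepwise = 1e-3, seed = 99L))
  expect_identical(s1, s2)
  s3 <- simulate_two_deme(neutral_cfg(plan = plan, n_msat = 2L,
                                      mu_stepwise = 1e-3, seed = 100L))
  expect_false(identical(s1, s3))
})

test_that("deme sizes stay constant and no new alleles arise without mutation", {
  plan <- data.frame(generation = c(0L, 5L), deme = 1L, size = 150L)
  cfg <- neutral_cfg(deme = 150L, gens = 5L, plan = plan, n_msat = 3L,
                     mu_stepwise = 0, seed = 7L)
  out <- simulate_two_deme(cfg)
  expect_equal(vapply(out, n_individuals, 0L), c(150L, 150L))
  init_alleles <- sprintf("%03d", c(10L, 12L, 14L))
  for (s in out) for (l in locus_names(s, "microsatellite")) {
    al <- locus_alleles(s, l)
    expect_true(all(stats::na.omit(c(al$a1, al$a2)) %in% init_alleles))
  }
  # candidate alleles always come from the configured set
  expect_true(all(unlist(lapply(out, function(s)
    locus_alleles(s, "candidate"))) %in% c("A", "B")))
})

test_that("stepwise mutation introduces +/-1 repeat neighbours only", {
  plan <- data.frame(generation = 10L, deme = 1L, size = 200L)
  cfg <- neutral_cfg(deme = 200L, gens = 10L, plan = plan, n_msat = 1L,
                     mu_stepwise = 0.02, seed = 11L)
  out <- simulate_two_deme(cfg)
  reps <- as.integer(unlist(locus_alleles(out[[1]], "msat01")))
  expect_true(all(reps >= 1L))
  expect_true(any(!reps %in% c(10L, 12L, 14L)))   # mutation did happen
})

test_that("neutral drift leaves candidate frequencies near their start", {
  # no migration, all fitness equal, large demes: change ~ N(0, pq t / 2N)
  plan <- data.frame(generation = 10L, deme = 1:2, size = 5000L)
  cfg <- neutral_cfg(deme = 10000L, gens = 10L, migration = 0,
                     plan = plan, seed = 21L)
  out <- simulate_two_deme(cfg)
  se_drift <- sqrt(0.5 * 0.5 * 10 / (2 * 10000))
  se_samp <- sqrt(0.5 * 0.5 / (2 * 5000))
  tol <- 4 * sqrt(se_drift^2 + se_samp^2)
  for (s in out) {
    p <- allele_frequencies(s, "candidate")["A"]
    expect_lt(abs(p - 0.5), tol)
  }
})

test_that("one generation of viability selection matches the recursion", {
  # w = (0.5, 1, 1) against the A homozygote, p0 = 0.5 -> p1 = 3/7
  plan <- data.frame(generation = 1L, deme = 1L, size = 100000L)
  cfg <- neutral_cfg(deme = 100000L, gens = 1L, migration = 0, plan = plan,
                     seed = 31L,
                     fitness_by_epoch = list("1" = list(before = c("A/A" = 0.5)),
                                             "2" = list(before = c("A/A" = 0.5))))
  out <- simulate_two_deme(cfg)
  p1 <- allele_frequencies(out[[1]], "candidate")["A"]
  expected <- 0.5 * (0.5 * 0.5 + 0.5) / (1 - 0.5 * 0.25)  # 0.428571
  se <- sqrt(expected * (1 - expected) / (2 * 100000))
  expect_lt(abs(p1 - expected), 3 * se)
})

test_that("oversized sampling plans and empty viable pools are rejected", {
  expect_error(
    neutral_cfg(deme = 24L,
                plan = data.frame(generation = 1L, deme = 1L, size = 30L)),
    "30 individuals from deme 1 of size 24")
  # fitness positive only for a genotype absent from deme 1
  cfg <- simulation_config(
    deme_sizes = c(50L, 50L), migration = diag(2),
    candidate_alleles = c("A", "B"),
    candidate_init_freqs = rbind(c(0, 1), c(1, 0)),
    fitness_by_epoch = list(
      "1" = list(before = c("A/A" = 1, "A/B" = 0, "B/B" = 0)),
      "2" = list(before = c("A/A" = 1, "A/B" = 0, "B/B" = 0))),
    n_generations = 1L, switch_generation = 1L,
    sampling_plan = data.frame(generation = 1L, deme = 1L, size = 5L),
    seed = 3L)
  expect_error(simulate_two_deme(cfg), "no viable parents in deme MEL")
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(neutral_cfg(migration = -0.1), "non-negative")
  bad_mig <- matrix(c(0.9, 0.2, 0.2, 0.9), 2, 2)
  expect_error(
    simulation_config(deme_sizes = c(10, 10), migration = bad_mig,
                      candidate_alleles = "A",
                      candidate_init_freqs = rbind(1, 1), seed = 1),
    "rows must sum to 1")
  expect_error(
    simulation_config(deme_sizes = c(10, 10), migration = diag(2),
                      candidate_alleles = c("A", "B"),
                      candidate_init_freqs = rbind(c(0.6, 0.5), c(0.5, 0.5)),
                      seed = 1),
    "sum to 1")
  expect_error(
    neutral_cfg(gens = 2L, switch_generation = 5L),
    "switch_generation")
})

test_that("deterministic trajectory obeys symmetry, selection and the switch", {
  # symmetric migration, neutral: both demes converge to the mean 0.5
  cfg <- simulation_config(
    deme_sizes = c(100L, 100L),
    migration = matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2, byrow = TRUE),
    candidate_alleles = c("A", "B"),
    candidate_init_freqs = rbind(c(0.8, 0.2), c(0.2, 0.8)),
    n_generations = 60L, switch_generation = 60L, seed = 1L)
  tr <- deterministic_trajectory(cfg)
  expect_equal(unname(tr[61, , "A"]), c(0.5, 0.5), tolerance = 1e-9)
  # selection recursion, one generation
  cfg2 <- simulation_config(
    deme_sizes = c(10L, 10L), migration = diag(2),
    candidate_alleles = c("A", "B"),
    candidate_init_freqs = rbind(c(0.5, 0.5), c(0.5, 0.5)),
    fitness_by_epoch = list("1" = list(before = c("A/A" = 0.5))),
    n_generations = 1L, switch_generation = 1L, seed = 1L)
  tr2 <- deterministic_trajectory(cfg2)
  expect_equal(unname(tr2[2, 1, "A"]), 3 / 7, tolerance = 1e-9)
  expect_equal(unname(tr2[2, 2, "A"]), 0.5)     # neutral deme unchanged
  # after the switch (no migration) frequencies freeze
  cfg3 <- simulation_config(
    deme_sizes = c(10L, 10L), migration = diag(2),
    candidate_alleles = c("A", "B"),
    candidate_init_freqs = rbind(c(0.7, 0.3), c(0.5, 0.5)),
    fitness_by_epoch = list("1" = list(before = c("A/A" = 0.2))),
    n_generations = 6L, switch_generation = 2L, seed = 1L)
  tr3 <- deterministic_trajectory(cfg3)
  expect_false(isTRUE(all.equal(tr3[2, 1, "A"], tr3[3, 1, "A"])))
  for (t in 4:7) expect_equal(tr3[t, 1, "A"], tr3[3, 1, "A"], tolerance = 1e-12)
})
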
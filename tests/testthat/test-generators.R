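test_that("expression generator recovers the configured ratio of change", {
  # true before-ratio 18, n = 50 per site: Monte-Carlo mean over replicate
  # datasets must sit within 3 standard errors of the truth
  reps <- 60
  est <- vapply(seq_len(reps), function(i) {
    cfg <- expression_config(mu = matrix(c(90, 5, 15, 5), 2, 2),
                             n_individuals = matrix(50L, 2, 2),
                             seed = 5000L + i)
    tab <- generate_expression(cfg)
    ratio_of_change(tab, "MEL", "SFM", epochs = "before")$ratio
  }, numeric(1))
  se <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 18), 3 * se + 0.5)  # small Jensen bias allowance
  expect_gt(mean(est), 15)
  expect_lt(mean(est), 21)
})

test_that("equal expression means give a ratio near one", {
  cfg <- expression_config(mu = matrix(5, 2, 2),
                           n_individuals = matrix(200L, 2, 2), seed = 42L)
  r <- ratio_of_change(generate_expression(cfg), "MEL", "SFM")
  expect_true(all(abs(r$ratio - 1) < 0.25))
})

test_that("library sizes honour the per-epoch bounds and their asymmetry", {
  cfg <- study_expression_config(seed = 8L)
  tab <- generate_expression(cfg)
  before <- tab$total_reads[tab$epoch == "before"]
  after <- tab$total_reads[tab$epoch == "after"]
  expect_true(all(before >= 1.83e6 & before <= 4.7e6))
  expect_true(all(after >= 11.89e6 & after <= 18.74e6))
  expect_gt(min(after), max(before))     # the two campaigns do not overlap
  expect_true(all(tab$mapped_reads >= 0))
  expect_true(all(tab$mapped_reads <= tab$total_reads))
})

test_that("expression config rejects invalid parameters", {
  expect_error(expression_config(mu = matrix(c(-1, 5, 5, 5), 2, 2)), "mu")
  expect_error(expression_config(mu = matrix(5, 2, 2), dispersion = 0),
               "dispersion")
})

test_that("water generator labels groups and respects degenerate sizes", {
  cfg <- study_water_config(seed = 4L, replicates = 1L)
  tab <- generate_water(cfg)
  # 2 sites x 2 epochs x 2 years x 1 replicate
  expect_equal(nrow(tab), 8L)
  expect_setequal(unique(tab$site), c("MEL", "SFM"))
  expect_true(all(c("EC", "pH", "DO") %in% names(tab)))
})

test_that("control-site epoch centroids coincide when means are equal", {
  cfg <- study_water_config(seed = 12L, replicates = 30L)
  tab <- generate_water(cfg)
  sfm <- tab[tab$site == "SFM", ]
  vars <- setdiff(names(tab), c("site", "year", "epoch"))
  d <- colMeans(sfm[sfm$epoch == "before", vars]) -
       colMeans(sfm[sfm$epoch == "after", vars])
  sds <- apply(sfm[, vars], 2, stats::sd)
  n <- sum(sfm$epoch == "before")
  expect_true(all(abs(d) < 3 * sds * sqrt(2 / n)))
})

test_that("non-positive-semidefinite covariance is rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)        # eigenvalues 3, -1
  expect_error(
    water_config(means = list(A = list(before = c(0, 0))),
                 covariance = bad, variables = c("x", "y")),
    "positive semidefinite")
  expect_error(
    water_config(means = list(A = list(before = c(0, 0))),
                 covariance = matrix(c(1, 0.5, 0.2, 1), 2, 2),
                 variables = c("x", "y")),
    "symmetric")
})
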
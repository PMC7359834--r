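test_that("allele frequencies exclude missing data and sum to one", {
  s <- one_locus_sample(c("A", "A", "A", NA), c("A", "B", "B", NA))
  fr <- allele_frequencies(s, "l1")
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(unname(fr["A"]), 4 / 6)
  s2 <- one_locus_sample(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(unname(allele_frequencies(s2, "l1")), c(0.5, 0.5))
  s3 <- one_locus_sample(c(NA, NA), c(NA, NA))
  expect_error(allele_frequencies(s3, "l1"), "no typed individuals")
})

test_that("heterozygosities match Nei's unbiased formula", {
  s <- one_locus_sample(c("A", "A"), c("B", "B"))
  expect_equal(heterozygosities(s, "l1"),
               c(Ho = 1, He = (4 / 3) * 0.5), tolerance = 1e-12)
  s2 <- one_locus_sample(c("A", "A", "A", "A"), c("A", "A", "A", "B"))
  expect_equal(heterozygosities(s2, "l1"),
               c(Ho = 0.25, He = (8 / 7) * (1 - 0.875^2 - 0.125^2)),
               tolerance = 1e-12)
  mono <- one_locus_sample(rep("A", 5), rep("A", 5))
  summ <- locus_summary(mono)
  expect_true(summ$monomorphic)
  expect_equal(summ$Ho, 0)
  expect_equal(summ$He, 0)
  expect_true(is.na(summ$Fis))
})

test_that("theta is 1 for samples fixed for different alleles", {
  sA <- one_locus_sample(rep("A", 8), rep("A", 8), site = "a")
  sB <- one_locus_sample(rep("B", 8), rep("B", 8), site = "b")
  expect_equal(unname(wc_f_statistics(list(sA, sB))$multilocus["theta"]), 1)
})

test_that("wc estimates equal the brute-force oracle on hand cases", {
  # exact HWE counts 1 AA / 2 AB / 1 BB: small-sample f is 1/7, not 0
  s <- one_locus_sample(c("A", "A", "A", "B"), c("A", "B", "B", "B"))
  w <- wc_f_statistics(list(s))
  o <- wc_oracle(list(s), "l1")
  expect_equal(unname(w$multilocus["f"]), o$f, tolerance = 1e-12)
  expect_equal(o$f, 1 / 7, tolerance = 1e-12)
  # a 2-sample, 1-locus, n = 4 each hand table
  s1 <- one_locus_sample(c("A", "A", "A", "B"), c("A", "A", "B", "B"))
  s2 <- one_locus_sample(c("A", "B", "B", "B"), c("B", "B", "B", "B"))
  w2 <- wc_f_statistics(list(s1, s2))
  o2 <- wc_oracle(list(s1, s2), "l1")
  expect_equal(unname(w2$multilocus["theta"]), o2$theta, tolerance = 1e-12)
  expect_equal(unname(w2$multilocus["f"]), o2$f, tolerance = 1e-12)
})

test_that("estimates are invariant to allele relabeling and sample order", {
  set.seed(71)
  s1 <- random_sample(n = 15, n_loci = 3)
  s2 <- random_sample(n = 12, n_loci = 3, year = 2001L)
  base <- wc_f_statistics(list(s1, s2))$multilocus
  # swap sample order
  expect_equal(wc_f_statistics(list(s2, s1))$multilocus, base,
               tolerance = 1e-12)
  # relabel alleles (A<->Z etc.) in both samples
  relabel <- function(s) {
    g <- s$geno
    g[] <- chartr("ABCD", "ZYXW", g)
    genotype_sample(s$site, s$year, g[, , 1], g[, , 2], s$loci$type)
  }
  expect_equal(wc_f_statistics(list(relabel(s1), relabel(s2)))$multilocus,
               base, tolerance = 1e-12)
})

test_that("multi-locus theta is the ratio of summed components", {
  set.seed(72)
  s1 <- random_sample(n = 18, n_loci = 4)
  s2 <- random_sample(n = 16, n_loci = 4, year = 2001L)
  w <- wc_f_statistics(list(s1, s2))
  per <- w$per_locus
  expect_equal(unname(w$multilocus["theta"]),
               sum(per$a) / sum(per$a + per$b + per$c), tolerance = 1e-12)
  # and is generally NOT the mean of per-locus thetas
  expect_false(isTRUE(all.equal(unname(w$multilocus["theta"]),
                                mean(per$theta))))
})

test_that("monomorphic loci are excluded and flagged", {
  a1 <- cbind(l1 = rep("A", 6), l2 = c("A", "B", "A", "B", "A", "B"))
  s1 <- genotype_sample("x", 1, a1, a1)
  s2 <- genotype_sample("y", 2, a1, a1)
  w <- wc_f_statistics(list(s1, s2))
  expect_equal(w$excluded_loci, "l1")
  expect_equal(w$per_locus$locus, "l2")
  a_mono <- cbind(l1 = rep("A", 6))
  expect_error(wc_f_statistics(list(genotype_sample("x", 1, a_mono, a_mono))),
               "monomorphic")
})

test_that("the F_IS permutation null detects an extreme heterozygote deficit", {
  s <- one_locus_sample(rep(c("A", "B"), each = 10), rep(c("A", "B"), each = 10))
  r <- permutation_test_fis(s, n_perm = 999, seed = 5)
  expect_lte(r$p.value, 0.01)
  expect_gt(r$f_obs, 0.99)
  expect_error(permutation_test_fis(s, n_perm = 0), "n_perm")
  # excess heterozygosity is not 'deficit': one-tailed p is large
  sx <- one_locus_sample(rep("A", 10), rep("B", 10))
  expect_gt(permutation_test_fis(sx, n_perm = 199, seed = 5)$p.value, 0.5)
})

test_that("F_IS permutation p-values are uniform under Hardy-Weinberg", {
  set.seed(81)
  reps <- 120
  pv <- vapply(seq_len(reps), function(i) {
    s <- hwe_sample(40, c(A = 0.6, B = 0.3, C = 0.1))
    permutation_test_fis(s, n_perm = 499)$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pv > 0))               # +1 smoothing: never exactly zero
})

test_that("the F_ST permutation test behaves at the extremes", {
  sA <- one_locus_sample(rep("A", 24), rep("A", 24), site = "a")
  sB <- one_locus_sample(rep("B", 24), rep("B", 24), site = "b")
  r <- permutation_test_fst(sA, sB, n_perm = 499, seed = 9)
  expect_equal(r$p.value, 1 / 500)        # minimal attainable p
  expect_equal(r$theta_obs, 1)
  # identical samples: observed theta is at/below the null's bulk
  set.seed(91)
  s <- random_sample(n = 20, n_loci = 2)
  r2 <- permutation_test_fst(s, s, n_perm = 199, seed = 10)
  expect_gt(r2$p.value, 0.5)
  mono <- one_locus_sample(rep("A", 4), rep("A", 4))
  expect_error(permutation_test_fst(mono, mono), "polymorphic")
})

test_that("permutation-path theta agrees with wc_f_statistics", {
  set.seed(92)
  s1 <- random_sample(n = 14, n_loci = 3, miss_rate = 0.1)
  s2 <- random_sample(n = 17, n_loci = 3, miss_rate = 0.1, year = 2001L)
  r <- permutation_test_fst(s1, s2, n_perm = 9, seed = 1)
  w <- wc_f_statistics(list(s1, s2), loci = r$loci)
  expect_equal(r$theta_obs, unname(w$multilocus["theta"]), tolerance = 1e-10)
})

test_that("pairwise_fst assembles symmetric matrices", {
  cfg <- study_config(seed = 14L, deme_size = 80L)
  samples <- simulate_two_deme(cfg)
  mel <- Filter(function(s) s$site == "MEL", samples)
  pw <- pairwise_fst(mel, loci = locus_names(mel[[1]], "microsatellite"),
                     n_perm = 99, seed = 2)
  expect_equal(pw$theta, t(pw$theta))
  expect_equal(diag(pw$theta), stats::setNames(rep(0, 4), rownames(pw$theta)))
  expect_true(all(pw$p.value[upper.tri(pw$p.value)] > 0))
})
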
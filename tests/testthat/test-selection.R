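test_that("genotype categories are correct, disjoint and exhaustive", {
  expect_equal(classify_genotype("GTCGC", "GTCGC", "GTCGC"),
               "focal_homozygote")
  expect_equal(classify_genotype("GTCGC", "CTCGC", "GTCGC"),
               "focal_heterozygote")
  expect_equal(classify_genotype("CTCGC", "CTCGC", "GTCGC"),
               "other_homozygote")
  expect_equal(classify_genotype("CTCGC", "CTTGC", "GTCGC"),
               "other_heterozygote")
  expect_error(classify_genotype(NA, "GTCGC", "GTCGC"), "missing")
  # property: every random pair lands in exactly one category
  set.seed(17)
  labs <- c("GTCGC", "CTCGC", "GTCGA", "CTCGA", "GTTGC")
  a1 <- sample(labs, 300, TRUE); a2 <- sample(labs, 300, TRUE)
  cats <- classify_genotype(a1, a2, "GTCGC")
  expect_true(all(cats %in% c("focal_homozygote", "focal_heterozygote",
                              "other_homozygote", "other_heterozygote")))
  expect_equal(cats == "focal_homozygote",
               a1 == "GTCGC" & a2 == "GTCGC")
  expect_equal(cats == "focal_heterozygote",
               xor(a1 == "GTCGC", a2 == "GTCGC"))
})

test_that("category counts total the typed individuals", {
  cfg <- study_config(seed = 23L, deme_size = 60L)
  s <- simulate_two_deme(cfg)[[1]]
  cc <- category_counts(s, "GTCGC")
  expect_equal(sum(cc$counts), n_individuals(s))
})

test_that("the exact Fisher test reproduces hand-enumerated p-values", {
  r <- fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2, 2))
  expect_equal(r$p.value, 34 / 70, tolerance = 1e-12)
  expect_equal(r$method, "enumeration")
  expect_equal(r$total_probability, 1, tolerance = 1e-9)
  # two identical rows: the observed table is modal
  expect_equal(fisher_exact_rxc(rbind(c(5, 3), c(5, 3)))$p.value, 1)
  expect_error(fisher_exact_rxc(matrix(c(-1, 1, 1, 1), 2, 2)),
               "non-negative")
  expect_error(fisher_exact_rxc(matrix(c(0.5, 1, 1, 1), 2, 2)), "integer")
})

test_that("Fisher p is invariant under row and column permutation", {
  set.seed(31)
  X <- matrix(rpois(8, 4), 2, 4)
  p0 <- fisher_exact_rxc(X)$p.value
  expect_equal(fisher_exact_rxc(X[2:1, ])$p.value, p0, tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(X[, sample(4)])$p.value, p0,
               tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(t(X))$p.value, p0, tolerance = 1e-12)
})

test_that("the Monte-Carlo fallback agrees with enumeration", {
  X <- matrix(c(8, 3, 2, 9, 5, 4), 2, 3)
  exact <- fisher_exact_rxc(X)
  mc <- fisher_exact_rxc(X, max_tables = 1, mc_draws = 2e4, seed = 77)
  expect_equal(mc$method, "monte-carlo")
  expect_lt(abs(mc$p.value - exact$p.value), 4 * mc$mc_se + 1e-3)
  # seeded: reproducible
  mc2 <- fisher_exact_rxc(X, max_tables = 1, mc_draws = 2e4, seed = 77)
  expect_identical(mc$p.value, mc2$p.value)
})

test_that("exact Mann-Whitney matches enumeration and its symmetries", {
  r0 <- mann_whitney_exact(1:4, 5:8)
  expect_equal(r0$p.value, 2 / 70, tolerance = 1e-12)
  r6 <- mann_whitney_exact(c(3, 4, 5, 8), c(1, 2, 6, 7))
  expect_equal(r6$U, 6)
  expect_equal(r6$p.value, 48 / 70, tolerance = 1e-12)
  expect_equal(mann_whitney_exact(2, 7)$p.value, 1)
  expect_error(mann_whitney_exact(numeric(0), 1), "non-empty")
  # null distribution: symmetric about n1*n2/2, total mass one
  d <- r6$distribution
  u <- as.numeric(names(d))
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(as.numeric(d), rev(as.numeric(d[match(16 - u, u)])))
  # agreement with the independent exact implementation in stats
  set.seed(33)
  for (i in 1:10) {
    x <- sample(1:100, 5); y <- sample(101:200, 6) - 100.5
    ours <- mann_whitney_exact(x, y)$p.value
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("fitness ratios follow the frequency-ratio definition", {
  mk_year <- function(year, counts) make_counts("MEL", year, counts)
  # identical frequencies in all years: every ratio is 1
  cl <- list(mk_year(2007, c(6, 10, 4, 4)), mk_year(2008, c(6, 10, 4, 4)),
             mk_year(2018, c(6, 10, 4, 4)), mk_year(2019, c(6, 10, 4, 4)))
  fit <- fitness_ratios(cl, c(2007, 2008), c(2018, 2019))
  expect_true(all(fit$values == 1))
  expect_true(all(fit$medians == 1))
  # before freq 0.60 both years, after 0.24 and 0.30 -> {0.4, 0.5}, median 0.45
  cl2 <- list(mk_year(2007, c(30, 10, 5, 5)), mk_year(2008, c(30, 10, 5, 5)),
              mk_year(2018, c(12, 18, 10, 10)), mk_year(2019, c(15, 15, 10, 10)))
  fit2 <- fitness_ratios(cl2, c(2007, 2008), c(2018, 2019))
  expect_equal(sort(unique(fit2$values["focal_homozygote", ])), c(0.4, 0.5))
  expect_equal(unname(fit2$medians["focal_homozygote"]), 0.45)
  # scaling every year's counts by a constant changes nothing
  cl3 <- lapply(cl2, function(x) make_counts(x$site, x$year, x$counts * 3))
  fit3 <- fitness_ratios(cl3, c(2007, 2008), c(2018, 2019))
  expect_equal(fit3$values, fit2$values, tolerance = 1e-12)
  # zero pooled before-frequency is a named error
  cl4 <- list(mk_year(2007, c(20, 4, 0, 0)), mk_year(2008, c(6, 10, 4, 4)),
              mk_year(2018, c(6, 10, 4, 4)), mk_year(2019, c(6, 10, 4, 4)))
  expect_error(fitness_ratios(cl4, c(2007, 2008), c(2018, 2019)),
               "zero before-frequency.*other.*2007")
  expect_error(fitness_ratios(cl, c(2007, 2008), c(2008, 2019)), "disjoint")
})

test_that("fitness comparisons use the exact Mann-Whitney enumeration", {
  est <- structure(list(
    site = "MEL",
    values = rbind(focal_homozygote = c(0.2, 0.3, 0.25, 0.35),
                   focal_heterozygote = c(1.5, 1.8, 1.6, 2.0),
                   other = c(1.5, 1.8, 1.6, 2.0)),
    medians = c(0.275, 1.7, 1.7)), class = "fitness_estimates")
  cmp <- compare_fitness(est)
  expect_equal(nrow(cmp), 3L)
  lo_hi <- cmp$category_a == "focal_homozygote"
  expect_true(all(abs(cmp$p.value[lo_hi] - 2 / 70) < 1e-12))
  # identical value multisets: p = 1
  same <- cmp[cmp$category_a == "focal_heterozygote", ]
  expect_equal(same$p.value, 1)
})

test_that("year-pair Fisher matrices mirror the category tables", {
  cl <- list(make_counts("MEL", 2007, c(15, 6, 2, 1)),
             make_counts("MEL", 2008, c(14, 7, 2, 1)),
             make_counts("MEL", 2018, c(3, 10, 6, 5)),
             make_counts("MEL", 2019, c(2, 11, 7, 4)))
  pv <- fisher_year_matrix(cl)
  expect_equal(dim(pv), c(4L, 4L))
  expect_true(all(is.na(diag(pv))))
  expect_equal(pv, t(pv))
  expect_lt(pv["2007", "2018"], 0.05)     # the engineered contrast
  expect_gt(pv["2007", "2008"], 0.5)      # near-identical tables
})
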
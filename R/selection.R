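#' Classify a candidate-locus genotype relative to the focal allele
#'
#' The four categories are: `focal_homozygote` (focal/focal),
#' `focal_heterozygote` (focal/other), `other_homozygote` (X/X with X
#' not focal) and `other_heterozygote` (X/Y, both not focal). The
#' categories are disjoint and cover every diploid genotype.
#'
#' @param allele1,allele2 Character vectors of allele labels (no
#'   missing values; drop untyped individuals upstream).
#' @param focal_allele The focal allele label.
#' @return Character vector of categories.
#' @export
classify_genotype <- function(allele1, allele2, focal_allele) {
  if (anyNA(allele1) || anyNA(allele2))
    stop("missing alleles cannot be classified; exclude untyped individuals")
  f1 <- allele1 == focal_allele
  f2 <- allele2 == focal_allele
  ifelse(f1 & f2, "focal_homozygote",
    ifelse(f1 | f2, "focal_heterozygote",
      ifelse(allele1 == allele2, "other_homozygote", "other_heterozygote")))
}

#' Count the four genotype categories at the candidate locus
#'
#' @param sample A [genotype_sample()] containing a locus of type
#'   `"candidate"` (or pass `locus`).
#' @param focal_allele The focal allele label.
#' @param locus Candidate locus name (default: the sample's candidate
#'   locus).
#' @return Object of class `category_counts`: list with `site`, `year`,
#'   `focal_allele` and integer `counts` over the four categories
#'   (total = typed individuals).
#' @export
category_counts <- function(sample, focal_allele, locus = NULL) {
  if (is.null(locus)) {
    locus <- locus_names(sample, "candidate")
    if (length(locus) != 1L)
      stop("sample must contain exactly one candidate locus (or pass `locus`)")
  }
  al <- locus_alleles(sample, locus)
  typed <- !is.na(al$a1)
  cats <- classify_genotype(al$a1[typed], al$a2[typed], focal_allele)
  lev <- c("focal_homozygote", "focal_heterozygote",
           "other_homozygote", "other_heterozygote")
  counts <- table(factor(cats, levels = lev))
  structure(list(site = sample$site, year = sample$year,
                 focal_allele = focal_allele,
                 counts = as.integer(counts)[seq_along(lev)] |>
                   stats::setNames(lev)),
            class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  cat(sprintf("category_counts %s/%d (focal %s): %s\n", x$site, x$year,
              x$focal_allele,
              paste(names(x$counts), x$counts, sep = "=", collapse = ", ")))
  invisible(x)
}

# ---- exact Fisher r x c -------------------------------------------------

#' Exact Fisher test for an r x c contingency table
#'
#' Two-sided by the probability-ordering criterion: with both margins
#' fixed, the p-value is the total multivariate-hypergeometric
#' probability of every table whose probability does not exceed that of
#' the observed table. Tables are fully enumerated when the universe of
#' tables with the given margins is no larger than `max_tables`;
#' otherwise a seeded Monte-Carlo estimate over `mc_draws` tables drawn
#' with [stats::r2dtable()] is returned together with its standard
#' error.
#'
#' @param table Non-negative integer matrix.
#' @param max_tables Enumeration cap (default 1e5 tables).
#' @param mc_draws Monte-Carlo sample size beyond the cap (>= 1e5).
#' @param seed Optional seed for the Monte-Carlo path.
#' @return List of class `fisher_rxc`: `p.value`, `method`
#'   (`"enumeration"` or `"monte-carlo"`), `n_tables` (enumerated
#'   universe size) or `mc_se`, and `total_probability` (enumeration
#'   sanity check; sums to 1).
#' @export
fisher_exact_rxc <- function(table, max_tables = 1e5, mc_draws = 1e5,
                             seed = NULL) {
  X <- as.matrix(table)
  if (any(X < 0) || any(X != round(X)))
    stop("table entries must be non-negative integers")
  X <- X[rowSums(X) > 0, colSums(X) > 0, drop = FALSE]
  if (nrow(X) < 2L || ncol(X) < 2L)
    return(list(p.value = 1, method = "degenerate", n_tables = 1L,
                total_probability = 1))
  rs <- rowSums(X); cs <- colSums(X); N <- sum(X)
  # log P(T) = sum(lgamma margins+1) - lgamma(N+1) - sum(lgamma cells+1)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  logp_obs <- log_const - sum(lgamma(X + 1))
  n_universe <- count_tables(rs, cs)
  if (n_universe <= max_tables) {
    logps <- enumerate_logp(rs, cs, log_const)
    tot <- sum(exp(logps))
    p <- sum(exp(logps[logps <= logp_obs + 1e-7]))
    structure(list(p.value = min(p, 1), method = "enumeration",
                   n_tables = n_universe, total_probability = tot),
              class = "fisher_rxc")
  } else {
    if (!is.null(seed)) set.seed(seed)
    draws <- stats::r2dtable(mc_draws, rs, cs)
    logps <- vapply(draws, function(tt) log_const - sum(lgamma(tt + 1)),
                    numeric(1))
    hits <- sum(logps <= logp_obs + 1e-7)
    p <- (hits + 1) / (mc_draws + 1)
    structure(list(p.value = p, method = "monte-carlo",
                   n_tables = n_universe,
                   mc_se = sqrt(p * (1 - p) / mc_draws)),
              class = "fisher_rxc")
  }
}

#' @export
print.fisher_rxc <- function(x, ...) {
  cat(sprintf("Fisher exact r x c: p = %.6g (%s)\n", x$p.value, x$method))
  invisible(x)
}

# number of non-negative integer tables with the given margins (DP count)
count_tables <- function(rs, cs) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, rem) {
    if (i == length(rs)) return(if (all(rem == 0)) 1 else 0)
    if (i == length(rs) - 1L)   # last row forced
      return(if (sum(rem) == rs[i + 1L]) 1 else 0)
    key <- paste(i, paste(rem, collapse = ","))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- 0
    for (row in row_fills(rs[i + 1L], rem))
      total <- total + rec(i + 1L, rem - row)
    memo[[key]] <- total
    total
  }
  rec(0L, cs)
}

# all ways to fill one row summing to s under per-column caps
row_fills <- function(s, caps) {
  cfill <- function(j, left) {
    if (j > length(caps)) return(if (left == 0) list(integer(0)) else list())
    cap_after <- if (j == length(caps)) 0 else sum(caps[(j + 1L):length(caps)])
    lo <- max(0L, left - cap_after)
    hi <- min(caps[j], left)
    if (lo > hi) return(list())
    out <- list()
    for (v in lo:hi)
      for (rest in cfill(j + 1L, left - v))
        out[[length(out) + 1L]] <- c(v, rest)
    out
  }
  cfill(1L, s)
}

# log-probabilities of every table with the given margins
enumerate_logp <- function(rs, cs, log_const) {
  r <- length(rs)
  out <- numeric(0)
  rec <- function(i, rem, acc) {
    if (i == r - 1L) {                     # last row forced by margins
      out[[length(out) + 1L]] <<- log_const + acc - sum(lgamma(rem + 1))
      return(invisible())
    }
    for (row in row_fills(rs[i + 1L], rem))
      rec(i + 1L, rem - row, acc - sum(lgamma(row + 1)))
  }
  rec(0L, cs, 0)
  unlist(out)
}

#' Fisher tests between all pairs of yearly category tables
#'
#' For one site, builds the year x year matrix of exact Fisher p-values
#' comparing the (by default unpooled, 4-category) genotype-category
#' counts of every pair of sampling years.
#'
#' @param counts_list List of [category_counts()] for one site.
#' @param pooled If `TRUE`, pool the two non-focal categories first.
#' @param ... Passed to [fisher_exact_rxc()].
#' @return Symmetric matrix of p-values with year labels (diagonal NA).
#' @export
fisher_year_matrix <- function(counts_list, pooled = FALSE, ...) {
  yrs <- vapply(counts_list, function(x) x$year, integer(1))
  m <- length(counts_list)
  pv <- matrix(NA_real_, m, m, dimnames = list(yrs, yrs))
  get_counts <- function(x) {
    if (!pooled) return(x$counts)
    c(x$counts[1:2],
      other = sum(x$counts[c("other_homozygote", "other_heterozygote")]))
  }
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    tab <- cbind(get_counts(counts_list[[i]]), get_counts(counts_list[[j]]))
    pv[i, j] <- pv[j, i] <- fisher_exact_rxc(tab, ...)$p.value
  }
  pv
}

# ---- exact Mann-Whitney -------------------------------------------------

#' Exact two-sided Mann-Whitney U test by full enumeration
#'
#' `U = #\{(i, j): x_i < y_j\}` plus 1/2 per cross-group tie. The exact
#' two-sided p-value is `2 * min(P(U <= u), P(U >= u))`, capped at 1,
#' where the null distribution of U is obtained by enumerating all
#' `choose(n1 + n2, n1)` assignments of the observed pooled values into
#' two groups of the observed sizes (so ties are handled exactly, by
#' enumeration over the observed multiset). Falls back to the normal
#' approximation of [stats::wilcox.test()] when the assignment universe
#' exceeds `max_combinations`.
#'
#' @param x,y Numeric value vectors (non-empty).
#' @param max_combinations Enumeration cap (default 5e5 assignments).
#' @return List of class `mw_exact`: `U`, `p.value`, `method`, and for
#'   the exact path `distribution` (probabilities indexed by attainable
#'   U values).
#' @export
mann_whitney_exact <- function(x, y, max_combinations = 5e5) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xx, yy)
    sum(outer(xx, yy, "<")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_stat(x, y)
  n_comb <- choose(n1 + n2, n1)
  if (n_comb > max_combinations) {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    return(structure(list(U = u_obs, p.value = wt$p.value,
                          method = "normal-approximation"),
                     class = "mw_exact"))
  }
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2L, function(sel)
    u_stat(pooled[sel], pooled[-sel]))
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  p <- min(1, 2 * min(p_le, p_ge))
  dist <- table(u_all) / length(u_all)
  structure(list(U = u_obs, p.value = p, method = "enumeration",
                 distribution = dist, n_assignments = length(u_all)),
            class = "mw_exact")
}

#' @export
print.mw_exact <- function(x, ...) {
  cat(sprintf("Mann-Whitney exact: U = %g, two-sided p = %.6g (%s)\n",
              x$U, x$p.value, x$method))
  invisible(x)
}

# ---- genotype-survival fitness ratios -----------------------------------

#' Genotype-survival fitness ratios across the intervention
#'
#' For each pooled genotype category (`focal_homozygote`,
#' `focal_heterozygote`, and `other` = the two non-focal categories
#' pooled, precisely to keep before-frequencies away from zero), the
#' fitness component is the ratio of the category's sample frequency in
#' an after-year to its frequency in a before-year. With two years on
#' each side of the intervention this yields four values per category
#' and site; the category medians summarize them.
#'
#' @param counts_list List of [category_counts()] for one site covering
#'   all four years.
#' @param before_years,after_years Integer year sets (must be disjoint
#'   and present in `counts_list`).
#' @return Object of class `fitness_estimates`: `site`, `values` (3 x
#'   (before x after) matrix of ratios, columns named `before_after`),
#'   `medians` (named per category).
#' @export
fitness_ratios <- function(counts_list,
                           before_years = c(2007L, 2011L),
                           after_years = c(2018L, 2019L)) {
  if (length(intersect(before_years, after_years)))
    stop("before and after year sets must be disjoint")
  yrs <- vapply(counts_list, function(x) x$year, integer(1))
  need <- c(before_years, after_years)
  if (!all(need %in% yrs))
    stop("missing year(s): ", paste(setdiff(need, yrs), collapse = ", "))
  site <- counts_list[[1L]]$site
  pooled_freq <- function(year) {
    ct <- counts_list[[match(year, yrs)]]$counts
    tot <- sum(ct)
    if (tot == 0) stop(sprintf("year %d has zero typed individuals", year))
    c(focal_homozygote = unname(ct["focal_homozygote"]),
      focal_heterozygote = unname(ct["focal_heterozygote"]),
      other = unname(sum(ct[c("other_homozygote", "other_heterozygote")]))) / tot
  }
  pairs <- expand.grid(before = before_years, after = after_years)
  vals <- matrix(NA_real_, 3L, nrow(pairs),
                 dimnames = list(c("focal_homozygote", "focal_heterozygote",
                                   "other"),
                                 paste(pairs$before, pairs$after, sep = "_")))
  for (k in seq_len(nrow(pairs))) {
    fb <- pooled_freq(pairs$before[k])
    fa <- pooled_freq(pairs$after[k])
    if (any(fb == 0))
      stop(sprintf(
        "zero before-frequency for category '%s' in year %d at site %s",
        names(fb)[fb == 0][1L], pairs$before[k], site))
    vals[, k] <- fa / fb
  }
  structure(list(site = site, values = vals,
                 medians = apply(vals, 1L, stats::median),
                 before_years = before_years, after_years = after_years),
            class = "fitness_estimates")
}

#' @export
print.fitness_estimates <- function(x, ...) {
  cat(sprintf("fitness_estimates for site %s (medians):\n", x$site))
  print(round(x$medians, 3))
  invisible(x)
}

#' Pairwise comparison of category fitness values
#'
#' Exact Mann-Whitney tests between the four-value fitness sets of every
#' pair of categories at one site. No multiplicity correction is
#' applied.
#'
#' @param estimates A [fitness_ratios()] result.
#' @return Data frame with columns `category_a`, `category_b`, `U`,
#'   `p.value`.
#' @export
compare_fitness <- function(estimates) {
  stopifnot(inherits(estimates, "fitness_estimates"))
  cats <- rownames(estimates$values)
  out <- list()
  for (i in seq_len(length(cats) - 1L)) for (j in (i + 1L):length(cats)) {
    mw <- mann_whitney_exact(estimates$values[i, ], estimates$values[j, ])
    out[[length(out) + 1L]] <- data.frame(
      category_a = cats[i], category_b = cats[j],
      U = mw$U, p.value = mw$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
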
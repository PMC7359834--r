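#' Allele frequencies at one locus of a sample
#'
#' Missing genotypes are excluded; frequencies are over the alleles
#' observed among typed individuals and sum to 1.
#'
#' @param sample A [genotype_sample()].
#' @param locus Locus name or index.
#' @return Named numeric vector of allele frequencies.
#' @export
allele_frequencies <- function(sample, locus) {
  al <- locus_alleles(sample, locus)
  v <- c(al$a1, al$a2)
  v <- v[!is.na(v)]
  if (!length(v))
    stop(sprintf("no typed individuals at locus '%s'", locus))
  tab <- table(v)
  fr <- as.numeric(tab) / sum(tab)
  names(fr) <- names(tab)
  fr
}

#' Observed and unbiased expected heterozygosity
#'
#' `Ho` is the fraction of heterozygous individuals among those typed;
#' `He` is Nei's unbiased estimator `(2n/(2n-1)) * (1 - sum(p^2))` with
#' `n` the number of typed individuals.
#'
#' @inheritParams allele_frequencies
#' @return Named numeric vector `c(Ho, He)`.
#' @export
heterozygosities <- function(sample, locus) {
  al <- locus_alleles(sample, locus)
  typed <- !is.na(al$a1)
  n <- sum(typed)
  if (n < 2L)
    stop(sprintf("need >= 2 typed individuals at locus '%s'", locus))
  ho <- mean(al$a1[typed] != al$a2[typed])
  p <- allele_frequencies(sample, locus)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  c(Ho = ho, He = he)
}

#' Per-locus diversity summary for one sample
#'
#' Reports the number of alleles, observed and unbiased expected
#' heterozygosity, the Weir-Cockerham within-sample f (F_IS) and, when
#' `n_perm > 0`, its allele-permutation p-value. Monomorphic loci are
#' flagged with `He = Ho = 0` and an undefined (NA) f, rather than
#' propagating NaN.
#'
#' @param sample A [genotype_sample()].
#' @param loci Locus names (default: all loci of the sample).
#' @param n_perm Permutations for the per-locus F_IS test (0 = skip).
#' @param seed Optional seed for the permutation null.
#' @param alternative Passed to [permutation_test_fis()].
#' @return A data frame with one row per locus: `locus`, `n_typed`,
#'   `n_alleles`, `Ho`, `He`, `Fis`, `p_fis`, `monomorphic`.
#' @export
locus_summary <- function(sample, loci = NULL, n_perm = 0L, seed = NULL,
                          alternative = "deficit") {
  if (is.null(loci)) loci <- locus_names(sample)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(loci, function(l) {
    al <- locus_alleles(sample, l)
    typed <- sum(!is.na(al$a1))
    if (typed == 0L)
      return(data.frame(locus = l, n_typed = 0L, n_alleles = 0L,
                        Ho = NA_real_, He = NA_real_, Fis = NA_real_,
                        p_fis = NA_real_, monomorphic = NA))
    p <- allele_frequencies(sample, l)
    mono <- length(p) < 2L
    if (mono || typed < 2L) {
      return(data.frame(locus = l, n_typed = typed,
                        n_alleles = length(p), Ho = 0, He = 0,
                        Fis = NA_real_, p_fis = NA_real_,
                        monomorphic = TRUE))
    }
    het <- heterozygosities(sample, l)
    fst <- wc_f_statistics(list(sample), loci = l)
    pf <- NA_real_
    if (n_perm > 0L)
      pf <- permutation_test_fis(sample, loci = l, n_perm = n_perm,
                                 alternative = alternative)$p.value
    data.frame(locus = l, n_typed = typed, n_alleles = length(p),
               Ho = unname(het["Ho"]), He = unname(het["He"]),
               Fis = unname(fst$multilocus["f"]), p_fis = pf,
               monomorphic = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- Weir & Cockerham (1984) variance components ------------------------

# Per-locus a/b/c sums over alleles for r samples.
# codes: list with $levels and per-sample integer vectors $a1, $a2.
# Returns c(a, b, c) (a = NA when r < 2) and the allele count.
wc_abc_locus <- function(codes) {
  K <- length(codes$levels)
  r_all <- length(codes$a1)
  n_i <- vapply(seq_len(r_all),
                function(i) sum(!is.na(codes$a1[[i]])), integer(1))
  use <- which(n_i >= 1L)
  r <- length(use)
  if (r == 0L || K < 2L)
    return(list(abc = c(a = NA_real_, b = NA_real_, c = NA_real_),
                n_alleles = K, r = r))
  n_i <- n_i[use]
  p <- matrix(0, r, K)     # allele freq per sample
  h <- matrix(0, r, K)     # het freq (carrying allele u) per sample
  for (ii in seq_len(r)) {
    i <- use[ii]
    a1 <- codes$a1[[i]]; a2 <- codes$a2[[i]]
    typed <- !is.na(a1)
    a1 <- a1[typed]; a2 <- a2[typed]
    cnt <- tabulate(a1, K) + tabulate(a2, K)
    p[ii, ] <- cnt / (2 * n_i[ii])
    is_het <- a1 != a2
    for (u in seq_len(K))
      h[ii, u] <- sum(is_het & (a1 == u | a2 == u)) / n_i[ii]
  }
  nbar <- mean(n_i)
  pbar <- colSums(n_i * p) / (r * nbar)
  hbar <- colSums(n_i * h) / (r * nbar)
  if (r >= 2L) {
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    s2 <- colSums(n_i * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  } else {
    nc <- NA_real_
    s2 <- rep(0, K)
  }
  rfrac <- if (r >= 2L) (r - 1) / r else 0
  a_u <- if (r >= 2L && nbar > 1)
    (nbar / nc) * (s2 - (pbar * (1 - pbar) - rfrac * s2 - hbar / 4) / (nbar - 1))
  else rep(NA_real_, K)
  b_u <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - rfrac * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_u <- hbar / 2
  list(abc = c(a = sum(a_u), b = sum(b_u), c = sum(c_u)),
       n_alleles = K, r = r)
}

#' Weir-Cockerham F-statistics
#'
#' Computes the variance-component estimators f (F_IS) and theta (F_ST)
#' of Weir & Cockerham (1984), per locus and multi-locus. Multi-locus
#' estimates are ratios of summed components (not averages of per-locus
#' ratios). Loci monomorphic across the analyzed samples are excluded
#' from the estimates and listed in `excluded_loci`.
#'
#' @param samples A list of [genotype_sample()] objects (>= 2 for theta,
#'   >= 1 for f).
#' @param loci Locus names (default: loci shared by all samples).
#' @return A list of class `wc_fstats`: `per_locus` (data frame with
#'   components `a`, `b`, `c` and estimates `f`, `theta`), `multilocus`
#'   (named vector `f`, `theta`), `excluded_loci`, `n_samples`.
#' @export
wc_f_statistics <- function(samples, loci = NULL) {
  if (inherits(samples, "genotype_sample")) samples <- list(samples)
  if (is.null(loci)) loci <- shared_loci(samples)$locus
  res <- lapply(loci, function(l) wc_abc_locus(locus_codes(samples, l)))
  poly <- vapply(res, function(x) x$n_alleles >= 2L, logical(1))
  if (!any(poly))
    stop("all requested loci are monomorphic; F-statistics undefined")
  per <- do.call(rbind, lapply(which(poly), function(i) {
    abc <- res[[i]]$abc
    data.frame(locus = loci[i], n_alleles = res[[i]]$n_alleles,
               a = abc["a"], b = abc["b"], c = abc["c"],
               f = 1 - abc["c"] / (abc["b"] + abc["c"]),
               theta = abc["a"] / sum(abc), row.names = NULL)
  }))
  A <- sum(per$a); B <- sum(per$b); C <- sum(per$c)
  multi <- c(f = 1 - C / (B + C), theta = A / (A + B + C))
  structure(list(per_locus = per, multilocus = multi,
                 excluded_loci = loci[!poly],
                 n_samples = length(samples)),
            class = "wc_fstats")
}

#' @export
print.wc_fstats <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F-statistics (%d samples, %d loci",
              x$n_samples, nrow(x$per_locus)))
  if (length(x$excluded_loci))
    cat(sprintf("; %d monomorphic excluded", length(x$excluded_loci)))
  cat(")\n")
  cat(sprintf("  multilocus f = %.5f, theta = %.5f\n",
              x$multilocus["f"], x$multilocus["theta"]))
  invisible(x)
}

# ---- permutation nulls --------------------------------------------------

#' Allele-permutation test of Hardy-Weinberg departure (F_IS)
#'
#' The null is built by shuffling alleles among individuals within the
#' sample, independently at each locus: this destroys any departure from
#' random union of gametes while preserving allele frequencies. The
#' p-value uses +1 smoothing, `p = (hits + 1) / (n_perm + 1)`, so it is
#' never exactly zero. The default one-tailed mode tests for
#' heterozygote deficit (f >= f_obs).
#'
#' @param sample A [genotype_sample()].
#' @param loci Loci to combine (default: all polymorphic loci); the test
#'   statistic is the multi-locus f over these loci.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional seed.
#' @param alternative `"deficit"` (one-tailed, default) or
#'   `"two.sided"`.
#' @return List with `f_obs`, `p.value`, `n_perm`, `alternative`.
#' @export
permutation_test_fis <- function(sample, loci = NULL, n_perm = 5000L,
                                 seed = NULL,
                                 alternative = c("deficit", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(loci)) {
    loci <- Filter(function(l) {
      al <- locus_alleles(sample, l)
      length(unique(stats::na.omit(c(al$a1, al$a2)))) >= 2L
    }, locus_names(sample))
  }
  if (!length(loci)) stop("no polymorphic locus to test")
  B <- numeric(n_perm); C <- numeric(n_perm)
  b_obs <- 0; c_obs <- 0
  for (l in loci) {
    codes <- locus_codes(list(sample), l)
    a1 <- codes$a1[[1L]]; a2 <- codes$a2[[1L]]
    typed <- !is.na(a1)
    a1 <- a1[typed]; a2 <- a2[typed]
    n <- length(a1)
    if (n < 2L) next
    K <- length(codes$levels)
    if (K < 2L) next
    pool <- c(a1, a2)
    cnt <- tabulate(pool, K)
    p <- cnt / (2 * n)
    bc <- fis_bc(p, n, het_freqs(a1, a2, K))
    b_obs <- b_obs + bc$b; c_obs <- c_obs + bc$c
    # permuted pairings, vectorized over permutations
    P1 <- matrix(0L, n_perm, n); P2 <- matrix(0L, n_perm, n)
    for (bidx in seq_len(n_perm)) {
      s <- pool[sample.int(2L * n)]
      P1[bidx, ] <- s[seq_len(n)]
      P2[bidx, ] <- s[n + seq_len(n)]
    }
    het <- P1 != P2
    for (u in seq_len(K)) {
      hu <- rowSums(het & (P1 == u | P2 == u)) / n
      bc_u <- fis_bc_allele(p[u], n, hu)
      B <- B + bc_u$b; C <- C + bc_u$c
    }
  }
  f_obs <- 1 - c_obs / (b_obs + c_obs)
  f_perm <- 1 - C / (B + C)
  hits <- switch(alternative,
    deficit = sum(f_perm >= f_obs - 1e-12),
    two.sided = sum(abs(f_perm) >= abs(f_obs) - 1e-12))
  list(f_obs = f_obs, p.value = (hits + 1) / (n_perm + 1),
       n_perm = n_perm, alternative = alternative, loci = loci)
}

# per-allele heterozygote frequencies of a sample (typed only)
het_freqs <- function(a1, a2, K) {
  is_het <- a1 != a2
  vapply(seq_len(K),
         function(u) sum(is_het & (a1 == u | a2 == u)), numeric(1)) /
    length(a1)
}

# single-sample (r = 1) WC components summed over alleles
fis_bc <- function(p, n, h) {
  b <- (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * h)
  list(b = sum(b), c = sum(h) / 2)
}
# same for one allele with h a vector across permutations
fis_bc_allele <- function(p, n, h) {
  list(b = (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * h),
       c = h / 2)
}

#' Individual-permutation test of differentiation (temporal F_ST)
#'
#' The null is built by permuting whole individuals between the two
#' samples, preserving sample sizes. One-tailed: the p-value is the
#' smoothed fraction of permutations with `theta >= theta_obs`.
#'
#' @param sample_a,sample_b Two [genotype_sample()] objects.
#' @param loci Loci to combine (default: shared polymorphic loci).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional seed.
#' @return List with `theta_obs`, `p.value`, `n_perm`, `loci`.
#' @export
permutation_test_fst <- function(sample_a, sample_b, loci = NULL,
                                 n_perm = 1000L, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  samples <- list(sample_a, sample_b)
  if (is.null(loci)) loci <- shared_loci(samples)$locus
  # keep loci polymorphic across the pooled pair
  keep <- vapply(loci, function(l) {
    lev <- locus_codes(samples, l)$levels
    length(lev) >= 2L
  }, logical(1))
  loci <- loci[keep]
  if (!length(loci))
    stop("no shared polymorphic locus between the two samples")
  nA <- n_individuals(sample_a); nB <- n_individuals(sample_b)
  n <- nA + nB
  # pooled per-individual dosage/het/typed matrices, columns = locus-alleles
  Dl <- list(); Hl <- list(); Tl <- list(); locus_of <- integer(0)
  for (li in seq_along(loci)) {
    codes <- locus_codes(samples, loci[li])
    K <- length(codes$levels)
    a1 <- c(codes$a1[[1L]], codes$a1[[2L]])
    a2 <- c(codes$a2[[1L]], codes$a2[[2L]])
    typed <- !is.na(a1)
    D <- matrix(0, n, K); H <- matrix(0, n, K)
    for (u in seq_len(K)) {
      D[, u] <- (a1 == u) + (a2 == u)
      H[, u] <- (a1 != a2) & (a1 == u | a2 == u)
    }
    D[!typed, ] <- 0; H[!typed, ] <- 0
    Dl[[li]] <- D; Hl[[li]] <- H; Tl[[li]] <- as.numeric(typed)
    locus_of <- c(locus_of, rep(li, K))
  }
  D <- do.call(cbind, Dl); H <- do.call(cbind, Hl)
  TT <- do.call(cbind, Tl)                       # n x L typed indicators
  totC <- colSums(D); totH <- colSums(H); totT <- colSums(TT)

  theta_from_counts <- function(C1, H1, T1) {
    # C1,H1: m x K_tot; T1: m x L; returns theta per row
    C2 <- matrix(rep(totC, each = nrow(C1)), nrow(C1)) - C1
    H2 <- matrix(rep(totH, each = nrow(H1)), nrow(H1)) - H1
    T2 <- matrix(rep(totT, each = nrow(T1)), nrow(T1)) - T1
    n1 <- T1[, locus_of, drop = FALSE]
    n2 <- T2[, locus_of, drop = FALSE]
    valid <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
    n1s <- pmax(n1, 1); n2s <- pmax(n2, 1)
    p1 <- C1 / (2 * n1s); p2 <- C2 / (2 * n2s)
    h1 <- H1 / n1s; h2 <- H2 / n2s
    nbar <- (n1 + n2) / 2
    nc <- 2 * n1 * n2 / (n1 + n2)
    pbar <- (C1 + C2) / (2 * (n1 + n2))
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (H1 + H2) / (n1 + n2)
    nbar1 <- pmax(nbar - 1, 1e-12)
    a <- (nbar / pmax(nc, 1e-12)) *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / nbar1)
    b <- (nbar / nbar1) *
      (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    a[!valid] <- 0; b[!valid] <- 0; cc[!valid] <- 0
    rowSums(a) / rowSums(a + b + cc)
  }

  obs_sel <- matrix(0, 1L, n); obs_sel[1L, seq_len(nA)] <- 1
  theta_obs <- theta_from_counts(obs_sel %*% D, obs_sel %*% H, obs_sel %*% TT)

  P <- matrix(0, n_perm, n)
  for (bidx in seq_len(n_perm))
    P[bidx, sample.int(n, nA)] <- 1
  theta_perm <- theta_from_counts(P %*% D, P %*% H, P %*% TT)

  hits <- sum(theta_perm >= theta_obs - 1e-12, na.rm = TRUE)
  list(theta_obs = as.numeric(theta_obs),
       p.value = (hits + 1) / (n_perm + 1),
       n_perm = n_perm, loci = loci)
}

#' Pairwise temporal F_ST matrix with permutation p-values
#'
#' Runs [permutation_test_fst()] for every pair of samples (typically
#' the sampling years of one site) and assembles the symmetric theta and
#' p-value matrices, mirroring the pairwise tables of temporal studies.
#'
#' @param samples A list of [genotype_sample()] objects (>= 2).
#' @param loci Loci to use (default: shared polymorphic loci per pair).
#' @param n_perm Permutations per pair.
#' @param seed Optional seed.
#' @param labels Row/column labels (default `site_year`).
#' @return A list of class `pairwise_fst` with `theta` and `p.value`
#'   matrices (diagonal 0 and NA respectively) and `n_perm`.
#' @export
pairwise_fst <- function(samples, loci = NULL, n_perm = 1000L, seed = NULL,
                         labels = NULL) {
  m <- length(samples)
  if (m < 2L) stop("need at least two samples")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels))
    labels <- vapply(samples, function(s) paste0(s$site, "_", s$year), "")
  th <- matrix(0, m, m, dimnames = list(labels, labels))
  pv <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    r <- permutation_test_fst(samples[[i]], samples[[j]], loci = loci,
                              n_perm = n_perm)
    th[i, j] <- th[j, i] <- r$theta_obs
    pv[i, j] <- pv[j, i] <- r$p.value
  }
  structure(list(theta = th, p.value = pv, n_perm = n_perm),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat(sprintf("pairwise Weir-Cockerham theta (%d permutations)\n", x$n_perm))
  print(round(x$theta, 4))
  invisible(x)
}
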
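# Independent oracles and small data builders shared across tests.

# --- brute-force Weir-Cockerham variance components ----------------------
# Independent scalar implementation working directly on raw two-column
# character genotype matrices (one matrix per sample, one locus), written
# plainly from the variance-component definitions. Returns the summed
# a/b/c components over alleles.
wc_oracle_locus <- function(mats) {
  mats <- lapply(mats, function(m) m[!is.na(m[, 1]) & !is.na(m[, 2]), ,
                                     drop = FALSE])
  mats <- mats[vapply(mats, nrow, 0L) > 0L]
  r <- length(mats)
  alleles <- sort(unique(unlist(mats)))
  n <- vapply(mats, nrow, 0L)
  nbar <- mean(n)
  a_tot <- 0; b_tot <- 0; c_tot <- 0
  for (al in alleles) {
    p <- numeric(r); h <- numeric(r)
    for (i in seq_len(r)) {
      m <- mats[[i]]
      p[i] <- sum(m == al) / (2 * n[i])
      h[i] <- sum((m[, 1] == al) != (m[, 2] == al)) / n[i]
    }
    pbar <- sum(n * p) / sum(n)
    hbar <- sum(n * h) / sum(n)
    if (r >= 2) {
      s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
      nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
    } else {
      a <- NA_real_
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
    }
    cc <- hbar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  list(a = a_tot, b = b_tot, c = c_tot,
       f = 1 - c_tot / (b_tot + c_tot),
       theta = if (r >= 2) a_tot / (a_tot + b_tot + c_tot) else NA_real_)
}

# multi-locus oracle over a list of genotype_sample objects
wc_oracle <- function(samples, loci) {
  A <- 0; B <- 0; C <- 0
  for (l in loci) {
    mats <- lapply(samples, function(s) {
      al <- tempsel::locus_alleles(s, l)
      cbind(al$a1, al$a2)
    })
    lev <- unique(stats::na.omit(unlist(mats)))
    if (length(lev) < 2) next                       # monomorphic: excluded
    o <- wc_oracle_locus(mats)
    A <- A + o$a; B <- B + o$b; C <- C + o$c
  }
  list(f = 1 - C / (B + C), theta = A / (A + B + C))
}

# --- closed-form two-sided Fisher p for a 2x2 table ----------------------
# Sum of hypergeometric probabilities not exceeding the observed one.
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# --- builders ------------------------------------------------------------
# genotype_sample with a single locus from explicit allele vectors
one_locus_sample <- function(a1, a2, site = "X", year = 2000L,
                             locus = "l1", type = "microsatellite") {
  tempsel::genotype_sample(
    site, year,
    matrix(a1, ncol = 1, dimnames = list(NULL, locus)),
    matrix(a2, ncol = 1), locus_type = type)
}

# random multi-locus sample (used for oracle-agreement sweeps)
random_sample <- function(n = 10L, n_loci = 2L, max_alleles = 4L,
                          miss_rate = 0.05, site = "R", year = 2000L) {
  a1 <- matrix(NA_character_, n, n_loci,
               dimnames = list(NULL, paste0("l", seq_len(n_loci))))
  a2 <- a1
  for (l in seq_len(n_loci)) {
    K <- sample(2:max_alleles, 1)
    freqs <- as.numeric(stats::rgamma(K, 1)); freqs <- freqs / sum(freqs)
    labs <- LETTERS[seq_len(K)]
    a1[, l] <- sample(labs, n, TRUE, prob = freqs)
    a2[, l] <- sample(labs, n, TRUE, prob = freqs)
    miss <- stats::runif(n) < miss_rate
    a1[miss, l] <- NA; a2[miss, l] <- NA
  }
  tempsel::genotype_sample(site, year, a1, a2)
}

# sample of n individuals drawn under exact random union of gametes
hwe_sample <- function(n, freqs, labs = names(freqs), site = "H",
                       year = 2000L) {
  if (is.null(labs)) labs <- LETTERS[seq_along(freqs)]
  one_locus_sample(sample(labs, n, TRUE, prob = freqs),
                   sample(labs, n, TRUE, prob = freqs),
                   site = site, year = year)
}

# category_counts object from raw counts (order: focal_homo, focal_het,
# other_homo, other_het)
make_counts <- function(site, year, counts, focal = "GTCGC") {
  structure(list(site = site, year = as.integer(year), focal_allele = focal,
                 counts = stats::setNames(as.integer(counts),
                   c("focal_homozygote", "focal_heterozygote",
                     "other_homozygote", "other_heterozygote"))),
            class = "category_counts")
}
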
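#' Diploid multi-locus genotype sample
#'
#' A `genotype_sample` holds the diploid genotypes of the individuals
#' collected at one site in one year -- the unit on which every
#' population-genetic statistic in the package operates. Alleles are
#' arbitrary string labels (candidate-gene haplotypes such as `"GTCGC"`,
#' or microsatellite repeat numbers as `"12"`); missing alleles are `NA`.
#' Allele pairs are unordered and stored lexicographically sorted.
#'
#' @param site Site label (e.g. `"MEL"`).
#' @param year Sampling year (integer).
#' @param allele1,allele2 Character matrices, individuals x loci, with
#'   column names naming the loci. `NA` marks a missing allele; a genotype
#'   is treated as missing if either allele is missing.
#' @param locus_type Character vector, one of `"candidate"` or
#'   `"microsatellite"` per locus (recycled if length 1).
#'
#' @return An object of class `genotype_sample` with components `site`,
#'   `year`, `loci` (data frame with columns `locus`, `type`) and `geno`
#'   (3-d character array individuals x loci x 2, pair-sorted).
#' @export
genotype_sample <- function(site, year, allele1, allele2,
                            locus_type = "microsatellite") {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "character"
  storage.mode(allele2) <- "character"
  if (!identical(dim(allele1), dim(allele2)))
    stop("allele1 and allele2 must have identical dimensions")
  if (nrow(allele1) < 1L)
    stop("a genotype_sample needs at least one individual")
  loci <- colnames(allele1)
  if (is.null(loci))
    loci <- paste0("locus", seq_len(ncol(allele1)))
  locus_type <- rep_len(locus_type, length(loci))
  if (!all(locus_type %in% c("candidate", "microsatellite")))
    stop("locus_type must be 'candidate' or 'microsatellite'")
  # either-allele-missing => whole genotype missing
  miss <- is.na(allele1) | is.na(allele2)
  allele1[miss] <- NA_character_
  allele2[miss] <- NA_character_
  # normalize unordered pairs
  swap <- !miss & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  geno <- array(c(allele1, allele2),
                dim = c(nrow(allele1), length(loci), 2L),
                dimnames = list(NULL, loci, c("a1", "a2")))
  structure(
    list(site = as.character(site), year = as.integer(year),
         loci = data.frame(locus = loci, type = locus_type,
                           stringsAsFactors = FALSE),
         geno = geno),
    class = "genotype_sample")
}

#' @export
print.genotype_sample <- function(x, ...) {
  cat(sprintf("genotype_sample: site %s, year %d, %d individuals, %d loci\n",
              x$site, x$year, n_individuals(x), nrow(x$loci)))
  cat(sprintf("  loci: %s\n",
              paste0(x$loci$locus, " (", substr(x$loci$type, 1, 5), ")",
                     collapse = ", ")))
  invisible(x)
}

#' Number of individuals in a genotype sample
#' @param sample A `genotype_sample`.
#' @return Integer count.
#' @export
n_individuals <- function(sample) {
  stopifnot(inherits(sample, "genotype_sample"))
  dim(sample$geno)[1L]
}

#' Extract the two allele vectors of one locus
#'
#' @param sample A `genotype_sample`.
#' @param locus Locus name or index.
#' @return A list with character vectors `a1`, `a2` (pair-sorted, `NA`
#'   for missing genotypes).
#' @export
locus_alleles <- function(sample, locus) {
  stopifnot(inherits(sample, "genotype_sample"))
  if (is.character(locus)) {
    idx <- match(locus, sample$loci$locus)
    if (is.na(idx)) stop(sprintf("unknown locus '%s'", locus))
  } else idx <- locus
  list(a1 = sample$geno[, idx, 1L], a2 = sample$geno[, idx, 2L])
}

#' Names of loci in a sample, optionally filtered by type
#' @param sample A `genotype_sample`.
#' @param type `NULL` (all), `"candidate"` or `"microsatellite"`.
#' @return Character vector of locus names.
#' @export
locus_names <- function(sample, type = NULL) {
  stopifnot(inherits(sample, "genotype_sample"))
  if (is.null(type)) return(sample$loci$locus)
  sample$loci$locus[sample$loci$type == type]
}

#' @export
format.genotype_sample <- function(x, ...) {
  sprintf("<genotype_sample %s/%d n=%d>", x$site, x$year, n_individuals(x))
}

# shared-locus table across a list of samples; errors on mismatched types
shared_loci <- function(samples) {
  stopifnot(length(samples) >= 1L)
  loci <- samples[[1L]]$loci
  for (s in samples[-1L]) {
    keep <- loci$locus %in% s$loci$locus
    loci <- loci[keep, , drop = FALSE]
  }
  loci
}

# convert one locus across samples into integer allele codes (levels shared)
locus_codes <- function(samples, locus) {
  a1 <- lapply(samples, function(s) locus_alleles(s, locus)$a1)
  a2 <- lapply(samples, function(s) locus_alleles(s, locus)$a2)
  lev <- sort(unique(stats::na.omit(c(unlist(a1), unlist(a2)))))
  list(levels = lev,
       a1 = lapply(a1, function(v) match(v, lev)),
       a2 = lapply(a2, function(v) match(v, lev)))
}

#' Pool several genotype samples into one
#'
#' Concatenates the individuals of samples sharing a locus list, e.g. to
#' form a pooled "before" or "after" sample for an epoch-level contrast.
#' The pooled sample carries the first sample's site and year labels.
#'
#' @param samples A list of `genotype_sample` objects with identical
#'   loci.
#' @return A single `genotype_sample`.
#' @export
pool_samples <- function(samples) {
  if (inherits(samples, "genotype_sample")) return(samples)
  stopifnot(length(samples) >= 1L)
  loci <- samples[[1L]]$loci
  for (s in samples)
    if (!identical(s$loci$locus, loci$locus))
      stop("all samples must share the same locus list")
  a1 <- do.call(rbind, lapply(samples, function(s)
    matrix(s$geno[, , 1L], ncol = nrow(loci))))
  a2 <- do.call(rbind, lapply(samples, function(s)
    matrix(s$geno[, , 2L], ncol = nrow(loci))))
  colnames(a1) <- colnames(a2) <- loci$locus
  genotype_sample(samples[[1L]]$site, samples[[1L]]$year, a1, a2, loci$type)
}

#' Convert genotype samples to a tidy long data frame
#'
#' One row per individual x locus, with both alleles; the inverse of
#' [samples_from_long()].
#'
#' @param samples A list of `genotype_sample` objects.
#' @return A data frame with columns `individual`, `site`, `year`,
#'   `locus`, `locus_type`, `allele1`, `allele2`.
#' @export
samples_to_long <- function(samples) {
  if (inherits(samples, "genotype_sample")) samples <- list(samples)
  do.call(rbind, lapply(samples, function(s) {
    n <- n_individuals(s)
    L <- nrow(s$loci)
    data.frame(
      individual = rep(sprintf("%s_%d_%03d", s$site, s$year, seq_len(n)), L),
      site = s$site, year = s$year,
      locus = rep(s$loci$locus, each = n),
      locus_type = rep(s$loci$type, each = n),
      allele1 = as.vector(s$geno[, , 1L]),
      allele2 = as.vector(s$geno[, , 2L]),
      stringsAsFactors = FALSE)
  }))
}

#' Rebuild genotype samples from a tidy long data frame
#'
#' @param df A data frame as produced by [samples_to_long()]; columns
#'   `individual`, `site`, `year`, `locus`, `allele1`, `allele2` are
#'   required, `locus_type` is optional (default microsatellite).
#' @return A list of `genotype_sample` objects, one per site x year.
#' @export
samples_from_long <- function(df) {
  need <- c("individual", "site", "year", "locus", "allele1", "allele2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!"locus_type" %in% names(df)) df$locus_type <- "microsatellite"
  key <- interaction(df$site, df$year, drop = TRUE)
  lapply(split(df, key), function(d) {
    loci <- unique(d[, c("locus", "locus_type")])
    inds <- unique(d$individual)
    a1 <- matrix(NA_character_, length(inds), nrow(loci),
                 dimnames = list(NULL, loci$locus))
    a2 <- a1
    i <- match(d$individual, inds)
    j <- match(d$locus, loci$locus)
    a1[cbind(i, j)] <- as.character(d$allele1)
    a2[cbind(i, j)] <- as.character(d$allele2)
    genotype_sample(d$site[1L], d$year[1L], a1, a2, loci$locus_type)
  })
}
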
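#' Configuration for the per-individual read-count generator
#'
#' Emulates the RNA-seq design of the study: a handful of individuals
#' per site and epoch, each with a library of `total_reads` filtered
#' reads (drawn log-uniformly between per-epoch bounds, reproducing the
#' strong library-size asymmetry between sequencing platforms) and a
#' number of reads mapped to the candidate-gene contig drawn from a
#' negative binomial whose mean is `mu * total_reads / 1e6`, `mu` being
#' the true normalized (per-million) expression of that site x epoch.
#'
#' @param mu Named list or 2x2 matrix of true per-million expression
#'   means, rows = sites (affected first), cols = epochs
#'   (`before`, `after`). All entries must be > 0.
#' @param dispersion Negative-binomial dispersion (1/size); > 0.
#' @param n_individuals 2x2 matrix (or scalar) of individuals per
#'   site x epoch.
#' @param total_read_bounds List with `before` and `after` length-2
#'   numeric bounds for the log-uniform library sizes.
#' @param sites Site labels, affected first.
#' @param years Named vector mapping epoch to calendar year label.
#' @param seed Integer seed.
#' @return An object of class `expression_config`.
#' @export
expression_config <- function(mu,
                              dispersion = 0.3,
                              n_individuals = matrix(c(3, 6, 3, 6), 2, 2),
                              total_read_bounds = list(
                                before = c(1.83e6, 4.7e6),
                                after = c(11.89e6, 18.74e6)),
                              sites = c("MEL", "SFM"),
                              years = c(before = 2012L, after = 2016L),
                              seed = 1L) {
  mu <- matrix(as.numeric(mu), 2L, 2L,
               dimnames = list(sites, c("before", "after")))
  if (any(mu <= 0)) stop("expression means mu must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  n_individuals <- matrix(as.integer(n_individuals), 2L, 2L,
                          dimnames = dimnames(mu))
  if (any(n_individuals < 1L)) stop("need >= 1 individual per site x epoch")
  for (ep in c("before", "after")) {
    b <- total_read_bounds[[ep]]
    if (length(b) != 2L || any(b < 1) || b[1L] > b[2L])
      stop("total_read_bounds must be increasing pairs >= 1")
  }
  structure(list(mu = mu, dispersion = dispersion,
                 n_individuals = n_individuals,
                 total_read_bounds = total_read_bounds,
                 sites = sites, years = years, seed = as.integer(seed)),
            class = "expression_config")
}

#' Generate a per-individual expression (read-count) table
#'
#' @param config An [expression_config()].
#' @return A data frame with columns `individual`, `site`, `year`,
#'   `epoch`, `mapped_reads`, `total_reads`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "expression_config"))
  set.seed(config$seed)
  rows <- list()
  for (ep in c("before", "after")) {
    b <- config$total_read_bounds[[ep]]
    for (s in 1:2) {
      n <- config$n_individuals[s, ep]
      total <- round(exp(stats::runif(n, log(b[1L]), log(b[2L]))))
      mean_mapped <- config$mu[s, ep] * total / 1e6
      mapped <- stats::rnbinom(n, size = 1 / config$dispersion,
                               mu = mean_mapped)
      rows[[paste(ep, s)]] <- data.frame(
        individual = sprintf("%s_%s_%02d", config$sites[s],
                             config$years[[ep]], seq_len(n)),
        site = config$sites[s], year = as.integer(config$years[[ep]]),
        epoch = ep, mapped_reads = as.integer(mapped),
        total_reads = as.integer(total), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for the water-chemistry generator
#'
#' Replicate measurements of the physicochemical variables (default 10:
#' EC, pH, TDS, NO3, NH4, Na, K, Ca, Mg, DO) are drawn from a
#' multivariate normal per site x epoch, so a pollution signal is a
#' shifted mean vector for the affected site before remediation.
#'
#' @param means Named list `[[site]][[epoch]]` of mean vectors over
#'   `variables`.
#' @param covariance Covariance matrix shared across groups (symmetric
#'   positive semidefinite), or a named list `[[site]][[epoch]]`.
#' @param variables Variable names.
#' @param replicates Replicate measurements per site x year (>= 1).
#' @param years Named list mapping epoch to the calendar years sampled.
#' @param seed Integer seed.
#' @return An object of class `water_config`.
#' @export
water_config <- function(means,
                         covariance,
                         variables = c("EC", "pH", "TDS", "NO3", "NH4",
                                       "Na", "K", "Ca", "Mg", "DO"),
                         replicates = 4L,
                         years = list(before = c(2007L, 2011L),
                                      after = c(2016L, 2017L)),
                         seed = 1L) {
  V <- length(variables)
  check_cov <- function(S) {
    S <- as.matrix(S)
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      stop("covariance must be symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("covariance must be positive semidefinite")
    S
  }
  if (!is.list(covariance)) covariance <- check_cov(covariance)
  else covariance <- lapply(covariance, function(x) lapply(x, check_cov))
  for (s in names(means)) for (ep in names(means[[s]]))
    if (length(means[[s]][[ep]]) != V)
      stop("each mean vector must match the number of variables")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(means = means, covariance = covariance,
                 variables = variables, replicates = as.integer(replicates),
                 years = years, seed = as.integer(seed)),
            class = "water_config")
}

#' Generate a replicate water-chemistry table
#'
#' @param config A [water_config()].
#' @return A data frame with columns `site`, `year`, `epoch`, then one
#'   column per variable.
#' @export
generate_water <- function(config) {
  stopifnot(inherits(config, "water_config"))
  set.seed(config$seed)
  rows <- list()
  for (s in names(config$means)) {
    for (ep in names(config$means[[s]])) {
      S <- if (is.list(config$covariance)) config$covariance[[s]][[ep]]
           else config$covariance
      for (yr in config$years[[ep]]) {
        X <- MASS::mvrnorm(config$replicates, mu = config$means[[s]][[ep]],
                           Sigma = S)
        X <- matrix(X, nrow = config$replicates)
        colnames(X) <- config$variables
        rows[[paste(s, yr)]] <- data.frame(
          site = s, year = as.integer(yr), epoch = ep, X,
          stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
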
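#' Correlation-matrix PCA of a samples x variables table
#'
#' Singular-value decomposition of the centered (and by default scaled)
#' data via [stats::prcomp()]. Scaling is the right default for water
#' chemistry, where variables live on incommensurable units (uS/cm,
#' mg/L, pH units). A fixed sign convention -- each loading column's
#' largest-magnitude entry is positive -- makes reported loadings
#' reproducible (eigenvector signs are otherwise arbitrary).
#'
#' @param x Numeric matrix or data frame (samples x variables); rows
#'   with missing values are dropped with a message.
#' @param center,scale Passed to [stats::prcomp()].
#' @return Object of class `pca_result`: `eigenvalues` (descending),
#'   `percent_variance`, `loadings` (variables x components, orthonormal
#'   columns), `scores` (samples x components), `center`, `scale`,
#'   `dropped_rows`.
#' @export
run_pca <- function(x, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 samples and 2 variables")
  keep <- stats::complete.cases(x)
  if (!all(keep))
    message(sprintf("dropping %d row(s) with missing values", sum(!keep)))
  x <- x[keep, , drop = FALSE]
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance variable(s) with scale = TRUE: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = center, scale. = scale)
  # sign convention: largest-|loading| entry of each component positive
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2L, flip, "*")
  scores <- sweep(pc$x, 2L, flip, "*")
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev,
                 percent_variance = 100 * ev / sum(ev),
                 loadings = rot, scores = scores,
                 center = pc$center, scale = pc$scale,
                 dropped_rows = which(!keep)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(4L, length(x$eigenvalues))
  cat("PCA (correlation/covariance eigendecomposition)\n")
  for (i in seq_len(k))
    cat(sprintf("  PC%d: eigenvalue %.3f (%.1f%% of variance)\n",
                i, x$eigenvalues[i], x$percent_variance[i]))
  invisible(x)
}

#' Group centroids and per-axis centroid separations on PCA scores
#'
#' @param result A [run_pca()] result.
#' @param grouping Factor/character vector of group labels covering all
#'   retained samples (e.g. `site:epoch`).
#' @param components Which components to report (default first two).
#' @return List of class `pca_groups`: `centroids` (groups x
#'   components) and `distances` (data frame of pairwise per-axis
#'   absolute centroid differences plus the euclidean distance over the
#'   chosen components).
#' @export
group_separation <- function(result, grouping, components = 1:2) {
  stopifnot(inherits(result, "pca_result"))
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(result$scores))
    stop("grouping must label every retained sample")
  groups <- unique(grouping)
  if (any(!nzchar(groups)))
    stop("empty group label")
  sc <- result$scores[, components, drop = FALSE]
  centroids <- do.call(rbind, lapply(groups, function(g)
    colMeans(sc[grouping == g, , drop = FALSE])))
  rownames(centroids) <- groups
  out <- list()
  if (length(groups) >= 2L) {
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      d <- abs(centroids[i, ] - centroids[j, ])
      out[[length(out) + 1L]] <- data.frame(
        group_a = groups[i], group_b = groups[j],
        t(d), euclidean = sqrt(sum(d^2)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(centroids = centroids,
                 distances = if (length(out)) do.call(rbind, out) else NULL),
            class = "pca_groups")
}

#' @export
print.pca_groups <- function(x, ...) {
  cat("PCA group centroids:\n")
  print(round(x$centroids, 3))
  invisible(x)
}
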
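#' Per-million normalization of mapped read counts
#'
#' `mapped_reads / total_reads * 1e6`: the standardized expression of
#' the candidate gene per million filtered reads, which makes libraries
#' of very different depth comparable.
#'
#' @param mapped_reads Non-negative integer vector.
#' @param total_reads Positive integer vector (recycled).
#' @return Numeric vector of normalized expression values.
#' @export
normalize_per_million <- function(mapped_reads, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (any(mapped_reads < 0)) stop("mapped_reads must be >= 0")
  if (any(mapped_reads > total_reads))
    stop("mapped_reads cannot exceed total_reads")
  mapped_reads / total_reads * 1e6
}

#' Between-site ratio of normalized expression, per epoch
#'
#' For each epoch, the ratio of the affected site's mean normalized
#' expression to the control site's. Comparing the before-epoch ratio
#' with the after-epoch ratio is the study's ratio-of-change statistic:
#' a drop indicates that the affected site's overexpression receded
#' after the intervention.
#'
#' @param table Data frame with columns `site`, `epoch`, `mapped_reads`,
#'   `total_reads` (as from [generate_expression()] or
#'   [read_expression_table()]).
#' @param affected_site,control_site Site labels.
#' @param epochs Epochs to report (default: all present).
#' @return Data frame with columns `epoch`, `mean_affected`,
#'   `mean_control`, `ratio`, `n_affected`, `n_control`.
#' @export
ratio_of_change <- function(table, affected_site, control_site,
                            epochs = NULL) {
  need <- c("site", "epoch", "mapped_reads", "total_reads")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(epochs)) epochs <- unique(table$epoch)
  table$norm <- normalize_per_million(table$mapped_reads, table$total_reads)
  rows <- lapply(epochs, function(ep) {
    aff <- table$norm[table$site == affected_site & table$epoch == ep]
    ctl <- table$norm[table$site == control_site & table$epoch == ep]
    if (!length(aff) || !length(ctl))
      stop(sprintf("both sites must be present in epoch '%s'", ep))
    mc <- mean(ctl)
    if (mc == 0) stop(sprintf("control mean is zero in epoch '%s'", ep))
    data.frame(epoch = ep, mean_affected = mean(aff), mean_control = mc,
               ratio = mean(aff) / mc,
               n_affected = length(aff), n_control = length(ctl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
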
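#' Read a per-individual expression (read-count) table
#'
#' @param path CSV path with header; required columns `site`,
#'   `mapped_reads`, `total_reads` and at least one of `epoch`, `year`.
#'   Extra columns are preserved.
#' @return Data frame; invariants (`mapped <= total`, `total > 0`) are
#'   checked.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "mapped_reads", "total_reads")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!any(c("epoch", "year") %in% names(df)))
    stop("missing required column(s): epoch or year")
  if (any(df$total_reads <= 0)) stop("total_reads must be positive")
  if (any(df$mapped_reads < 0) || any(df$mapped_reads > df$total_reads))
    stop("mapped_reads must lie in [0, total_reads]")
  df
}

#' Read a water-chemistry table
#'
#' @param path CSV path with header; required columns `site` and `year`
#'   (optionally `epoch`); every remaining column is treated as a
#'   numeric chemistry variable.
#' @return Data frame.
#' @export
read_water_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("site", "year")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  vars <- setdiff(names(df), c("site", "year", "epoch"))
  if (!length(vars)) stop("no chemistry variables found")
  for (v in vars) df[[v]] <- as.numeric(df[[v]])
  df
}

#' Write genotype samples as a tidy CSV
#'
#' One row per individual x locus with both alleles; see
#' [samples_to_long()].
#'
#' @param samples List of [genotype_sample()] objects.
#' @param path Output CSV path.
#' @return Invisibly, the long data frame written.
#' @export
write_genotype_csv <- function(samples, path) {
  df <- samples_to_long(samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a tidy genotype CSV into genotype samples
#'
#' @param path CSV path as written by [write_genotype_csv()]; required
#'   columns `individual`, `site`, `year`, `locus`, `allele1`,
#'   `allele2`.
#' @return List of [genotype_sample()] objects, one per site x year.
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$year <- as.integer(df$year)
  df$allele1[df$allele1 == ""] <- NA_character_
  df$allele2[df$allele2 == ""] <- NA_character_
  samples_from_long(df)
}
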
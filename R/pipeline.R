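#' Configuration for the end-to-end pipeline
#'
#' Bundles inputs (simulated or read from disk), analysis switches and
#' reproducibility settings for [run_pipeline()]. Every source of
#' randomness (simulation, both permutation nulls, Monte-Carlo Fisher)
#' is derived from the single `seed`, with a fixed per-stage offset, so
#' disabling one analysis does not perturb another's results.
#'
#' @param genotypes List of [genotype_sample()] objects, a path to a
#'   Genepop or tidy genotype CSV file, or `NULL` to simulate from
#'   `simulation`.
#' @param simulation A [simulation_config()] (default [study_config()]),
#'   used when `genotypes` is `NULL`.
#' @param expression A data frame, a CSV path, an [expression_config()],
#'   or `NULL` to generate from [study_expression_config()].
#' @param water A data frame, a CSV path, a [water_config()], or `NULL`
#'   to generate from [study_water_config()].
#' @param analyses Character subset of
#'   `c("popgen", "selection", "expression", "water")`.
#' @param focal_allele Focal candidate allele label.
#' @param before_years,after_years Disjoint year sets.
#' @param affected_site,control_site Site labels.
#' @param n_perm_fis,n_perm_fst Permutation counts for the F_IS and
#'   F_ST nulls.
#' @param seed Integer master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL,
                            simulation = NULL,
                            expression = NULL,
                            water = NULL,
                            analyses = c("popgen", "selection",
                                         "expression", "water"),
                            focal_allele = "GTCGC",
                            before_years = c(2007L, 2008L),
                            after_years = c(2018L, 2019L),
                            affected_site = "MEL",
                            control_site = "SFM",
                            n_perm_fis = 5000L,
                            n_perm_fst = 1000L,
                            seed = 1L) {
  if (!length(analyses)) stop("at least one analysis must be enabled")
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (length(intersect(before_years, after_years)))
    stop("before_years and after_years must be disjoint")
  structure(list(genotypes = genotypes, simulation = simulation,
                 expression = expression, water = water,
                 analyses = analyses, focal_allele = focal_allele,
                 before_years = as.integer(before_years),
                 after_years = as.integer(after_years),
                 affected_site = affected_site,
                 control_site = control_site,
                 n_perm_fis = as.integer(n_perm_fis),
                 n_perm_fst = as.integer(n_perm_fst),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full simulate/analyze/report pipeline
#'
#' Executes the enabled analyses and writes a report bundle to
#' `out_dir`: per-sample diversity and F_IS tables, pairwise temporal
#' F_ST matrices (microsatellites and candidate locus, per site),
#' Fisher year-pair p-value matrices, fitness ratios with pairwise
#' Mann-Whitney comparisons, the expression ratio-of-change table, PCA
#' eigenvalues/loadings/scores/centroids, a JSON run manifest (seed,
#' permutation counts, package version, input digests) and a plain-text
#' summary. Identical config + seed gives a byte-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  tsv <- function(df, name, rownames = FALSE) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = rownames,
                       col.names = if (rownames) NA else TRUE)
  }

  # -- inputs --------------------------------------------------------------
  samples <- NULL
  if (any(c("popgen", "selection") %in% config$analyses)) {
    g <- config$genotypes
    if (is.null(g)) {
      simcfg <- config$simulation
      if (is.null(simcfg)) simcfg <- study_config(seed = config$seed)
      samples <- simulate_two_deme(simcfg)
    } else if (is.character(g)) {
      samples <- if (grepl("\\.csv$", g, ignore.case = TRUE))
        read_genotype_csv(g) else read_genepop(g)
    } else samples <- g
  }

  sites <- unique(vapply(samples, function(s) s$site, ""))

  # -- popgen --------------------------------------------------------------
  if ("popgen" %in% config$analyses) {
    set.seed(config$seed + 101L)
    sumrows <- lapply(samples, function(s) {
      d <- locus_summary(s, n_perm = config$n_perm_fis)
      cbind(site = s$site, year = s$year, d)
    })
    res$locus_summary <- do.call(rbind, sumrows)
    tsv(res$locus_summary, "locus_summary.tsv")
    res$fst <- list()
    for (site in sites) {
      ss <- Filter(function(s) s$site == site, samples)
      ss <- ss[order(vapply(ss, function(s) s$year, 0L))]
      if (length(ss) < 2L) next
      for (type in c("microsatellite", "candidate")) {
        loci <- locus_names(ss[[1L]], type)
        if (!length(loci)) next
        set.seed(config$seed + 211L)
        pw <- tryCatch(
          pairwise_fst(ss, loci = loci, n_perm = config$n_perm_fst),
          error = function(e) NULL)
        if (is.null(pw)) next
        key <- paste0(type, "_", site)
        res$fst[[key]] <- pw
        tsv(as.data.frame(pw$theta), paste0("fst_", key, ".tsv"),
            rownames = TRUE)
        tsv(as.data.frame(pw$p.value), paste0("fst_p_", key, ".tsv"),
            rownames = TRUE)
      }
    }
  }

  # -- selection -----------------------------------------------------------
  if ("selection" %in% config$analyses) {
    res$selection <- list()
    for (site in sites) {
      ss <- Filter(function(s) s$site == site, samples)
      ss <- ss[order(vapply(ss, function(s) s$year, 0L))]
      counts <- lapply(ss, category_counts,
                       focal_allele = config$focal_allele)
      cc <- do.call(rbind, lapply(counts, function(x)
        data.frame(site = x$site, year = x$year, t(x$counts))))
      tsv(cc, paste0("category_counts_", site, ".tsv"))
      set.seed(config$seed + 307L)
      fyear <- fisher_year_matrix(counts, seed = config$seed + 307L)
      tsv(as.data.frame(fyear), paste0("fisher_", site, ".tsv"),
          rownames = TRUE)
      # pooled before-vs-after epoch contrast (Fisher + temporal F_ST)
      yrs <- vapply(ss, function(s) s$year, 0L)
      bsel <- yrs %in% config$before_years
      asel <- yrs %in% config$after_years
      epoch_tests <- NULL
      if (any(bsel) && any(asel)) {
        bct <- Reduce(`+`, lapply(counts[bsel], function(x) x$counts))
        act <- Reduce(`+`, lapply(counts[asel], function(x) x$counts))
        pfish <- fisher_exact_rxc(cbind(bct, act),
                                  seed = config$seed + 311L)$p.value
        set.seed(config$seed + 313L)
        pfst <- permutation_test_fst(pool_samples(ss[bsel]),
                                     pool_samples(ss[asel]),
                                     loci = locus_names(ss[[1L]], "candidate"),
                                     n_perm = config$n_perm_fst)
        epoch_tests <- data.frame(site = site, test = c("fisher", "fst"),
                                  statistic = c(NA, pfst$theta_obs),
                                  p.value = c(pfish, pfst$p.value))
        tsv(epoch_tests, paste0("before_after_", site, ".tsv"))
      }
      fit <- tryCatch(
        fitness_ratios(counts, config$before_years, config$after_years),
        error = function(e) e)
      if (inherits(fit, "error")) {
        res$selection[[site]] <- list(counts = counts, fisher = fyear,
                                      epoch_tests = epoch_tests,
                                      fitness_error = conditionMessage(fit))
        next
      }
      cmp <- compare_fitness(fit)
      tsv(data.frame(category = rownames(fit$values), fit$values,
                     median = fit$medians, check.names = FALSE),
          paste0("fitness_", site, ".tsv"))
      tsv(cmp, paste0("fitness_tests_", site, ".tsv"))
      res$selection[[site]] <- list(counts = counts, fisher = fyear,
                                    fitness = fit, comparisons = cmp,
                                    epoch_tests = epoch_tests)
    }
  }

  # -- expression ----------------------------------------------------------
  if ("expression" %in% config$analyses) {
    ex <- config$expression
    if (is.null(ex)) ex <- study_expression_config(seed = config$seed + 401L)
    if (inherits(ex, "expression_config")) ex <- generate_expression(ex)
    else if (is.character(ex)) ex <- read_expression_table(ex)
    if (!"epoch" %in% names(ex))
      ex$epoch <- ifelse(ex$year %in% config$before_years, "before", "after")
    res$expression <- ratio_of_change(ex, config$affected_site,
                                      config$control_site)
    ex$normalized <- normalize_per_million(ex$mapped_reads, ex$total_reads)
    tsv(ex, "expression_long.tsv")
    tsv(res$expression, "expression_ratio.tsv")
  }

  # -- water ---------------------------------------------------------------
  if ("water" %in% config$analyses) {
    wt <- config$water
    if (is.null(wt)) wt <- study_water_config(seed = config$seed + 503L)
    if (inherits(wt, "water_config")) wt <- generate_water(wt)
    else if (is.character(wt)) wt <- read_water_table(wt)
    vars <- setdiff(names(wt), c("site", "year", "epoch"))
    pca <- run_pca(wt[, vars])
    if (!"epoch" %in% names(wt))
      wt$epoch <- ifelse(wt$year %in% config$before_years, "before", "after")
    grouping <- paste(wt$site, wt$epoch, sep = ":")
    if (length(pca$dropped_rows)) grouping <- grouping[-pca$dropped_rows]
    groups <- group_separation(pca, grouping)
    res$water <- list(pca = pca, groups = groups)
    tsv(data.frame(component = seq_along(pca$eigenvalues),
                   eigenvalue = pca$eigenvalues,
                   percent_variance = pca$percent_variance),
        "water_eigenvalues.tsv")
    tsv(as.data.frame(pca$loadings), "water_loadings.tsv", rownames = TRUE)
    tsv(data.frame(wt[, c("site", "year", "epoch")], pca$scores),
        "water_scores.tsv")
    tsv(as.data.frame(groups$centroids), "water_centroids.tsv",
        rownames = TRUE)
    if (!is.null(groups$distances))
      tsv(groups$distances, "water_centroid_distances.tsv")
  }

  # -- manifest and summary ------------------------------------------------
  manifest <- list(
    package = "tempsel",
    version = as.character(utils::packageVersion("tempsel")),
    seed = config$seed,
    n_perm_fis = config$n_perm_fis,
    n_perm_fst = config$n_perm_fst,
    analyses = config$analyses,
    focal_allele = config$focal_allele,
    before_years = config$before_years,
    after_years = config$after_years,
    files = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  summ <- c(
    sprintf("tempsel pipeline (seed %d)", config$seed),
    sprintf("analyses: %s", paste(config$analyses, collapse = ", ")),
    if (!is.null(res$expression))
      sprintf("expression ratio (affected/control): %s",
              paste(sprintf("%s = %.2f", res$expression$epoch,
                            res$expression$ratio), collapse = ", ")),
    if (!is.null(res$selection))
      vapply(names(res$selection), function(site) {
        sel <- res$selection[[site]]
        if (!is.null(sel$fitness))
          sprintf("site %s fitness medians: %s", site,
                  paste(sprintf("%s = %.2f", names(sel$fitness$medians),
                                sel$fitness$medians), collapse = ", "))
        else sprintf("site %s fitness: %s", site, sel$fitness_error)
      }, ""))
  writeLines(summ, file.path(out_dir, "summary.txt"))
  invisible(res)
}
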
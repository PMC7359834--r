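#' Write genotype samples to a Genepop file
#'
#' One `POP` block per sample (site x year), individuals as
#' `id ,  aaabbb cccddd ...` with 3-digit diploid allele codes and
#' `000000` for missing genotypes. Loci whose allele labels are not
#' plain integers (the candidate-gene haplotypes) are encoded through an
#' allele dictionary that is emitted as a sidecar CSV
#' (`<path>.alleles.csv`, columns `locus`, `allele`, `code`); integer
#' labels (microsatellite repeat numbers) are used as codes directly.
#'
#' @param samples List of [genotype_sample()] objects sharing a locus
#'   list.
#' @param path Output file path.
#' @param title Title line (first line of the file).
#' @return Invisibly, the allele dictionary data frame (possibly empty).
#' @export
write_genepop <- function(samples, path,
                          title = "tempsel genotype export") {
  if (inherits(samples, "genotype_sample")) samples <- list(samples)
  loci <- samples[[1L]]$loci
  for (s in samples)
    if (!identical(s$loci$locus, loci$locus))
      stop("all samples must share the same locus list")
  # dictionary for non-integer allele labels
  dict <- list()
  code_of <- list()
  for (l in loci$locus) {
    labs <- sort(unique(stats::na.omit(unlist(
      lapply(samples, function(s) unlist(locus_alleles(s, l)))))))
    if (length(labs) > 999L)
      stop(sprintf("locus '%s' has %d alleles; Genepop codes allow <= 999",
                   l, length(labs)))
    if (all(grepl("^[0-9]+$", labs))) {
      if (any(as.integer(labs) > 999L))
        stop(sprintf("locus '%s' has numeric alleles > 999", l))
      code_of[[l]] <- stats::setNames(as.integer(labs), labs)
    } else {
      code_of[[l]] <- stats::setNames(seq_along(labs), labs)
      dict[[l]] <- data.frame(locus = l, allele = labs,
                              code = seq_along(labs),
                              stringsAsFactors = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci$locus, con)
  for (s in samples) {
    writeLines("POP", con)
    n <- n_individuals(s)
    ids <- sprintf("%s_%d_%03d", s$site, s$year, seq_len(n))
    geno_str <- vapply(seq_len(n), function(i) {
      paste(vapply(loci$locus, function(l) {
        al <- locus_alleles(s, l)
        a1 <- al$a1[i]; a2 <- al$a2[i]
        if (is.na(a1)) "000000"
        else sprintf("%03d%03d", code_of[[l]][a1], code_of[[l]][a2])
      }, ""), collapse = " ")
    }, "")
    writeLines(paste(ids, ", ", geno_str), con)
  }
  dict <- if (length(dict)) do.call(rbind, dict)
          else data.frame(locus = character(), allele = character(),
                          code = integer())
  rownames(dict) <- NULL
  utils::write.csv(dict, paste0(path, ".alleles.csv"), row.names = FALSE)
  invisible(dict)
}

#' Read a Genepop file into genotype samples
#'
#' Accepts the common dialect: a title line, locus names (one per line
#' or comma-separated on one line), `POP` separators, and per-individual
#' lines `id , code1 code2 ...` with 2- or 3-digit diploid allele codes
#' (`00`/`000` = missing). Individual ids of the form `SITE_YEAR_nnn`
#' (as written by [write_genepop()]) recover site and year; otherwise
#' the POP index is used as the site label. If an allele dictionary is
#' present (argument or `<path>.alleles.csv` sidecar) its loci are
#' decoded to string labels and typed `"candidate"`; all other codes
#' become zero-padded 3-digit labels typed `"microsatellite"`.
#'
#' @param path Genepop file path.
#' @param allele_dictionary Optional data frame (`locus`, `allele`,
#'   `code`); default: the sidecar CSV next to `path`, if it exists.
#' @return List of [genotype_sample()] objects in file order.
#' @export
read_genepop <- function(path, allele_dictionary = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a Genepop file: too few lines")
  if (is.null(allele_dictionary)) {
    side <- paste0(path, ".alleles.csv")
    if (file.exists(side))
      allele_dictionary <- utils::read.csv(side, stringsAsFactors = FALSE,
                                           colClasses = c(allele = "character"))
  }
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("no POP separator found")
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci[nzchar(trimws(loci))])
  if (!length(loci)) stop("no locus names before first POP")
  L <- length(loci)
  pop_starts <- which(is_pop)
  pop_ends <- c(pop_starts[-1L] - 1L, length(lines))
  decode <- function(code, locus) {
    if (code == 0L) return(NA_character_)
    if (!is.null(allele_dictionary) &&
        locus %in% allele_dictionary$locus) {
      d <- allele_dictionary[allele_dictionary$locus == locus, ]
      hit <- d$allele[match(code, d$code)]
      if (is.na(hit))
        stop(sprintf("code %d at locus '%s' missing from allele dictionary",
                     code, locus))
      return(hit)
    }
    sprintf("%03d", code)
  }
  cand_loci <- if (!is.null(allele_dictionary))
    unique(allele_dictionary$locus) else character(0)
  out <- vector("list", length(pop_starts))
  for (b in seq_along(pop_starts)) {
    rows <- (pop_starts[b] + 1L):pop_ends[b]
    rows <- rows[rows <= length(lines) & nzchar(trimws(lines[rows])) &
                   !is_pop[rows]]
    if (!length(rows))
      stop(sprintf("empty POP block starting at line %d", pop_starts[b]))
    ids <- character(length(rows))
    a1 <- matrix(NA_character_, length(rows), L,
                 dimnames = list(NULL, loci))
    a2 <- a1
    for (k in seq_along(rows)) {
      ln <- lines[rows[k]]
      parts <- strsplit(ln, ",", fixed = TRUE)[[1L]]
      if (length(parts) < 2L)
        stop(sprintf("line %d: expected 'id , genotypes'", rows[k]))
      ids[k] <- trimws(parts[1L])
      toks <- strsplit(trimws(paste(parts[-1L], collapse = ",")),
                       "[[:space:]]+")[[1L]]
      if (length(toks) != L)
        stop(sprintf("line %d: %d genotype fields for %d loci",
                     rows[k], length(toks), L))
      for (l in seq_len(L)) {
        tok <- toks[l]
        if (!grepl("^[0-9]+$", tok))
          stop(sprintf("line %d: non-numeric genotype code '%s'",
                       rows[k], tok))
        w <- nchar(tok)
        if (!w %in% c(4L, 6L))
          stop(sprintf("line %d: genotype code '%s' is not 4 or 6 digits",
                       rows[k], tok))
        half <- w %/% 2L
        c1 <- as.integer(substr(tok, 1L, half))
        c2 <- as.integer(substr(tok, half + 1L, w))
        if (c1 == 0L || c2 == 0L) next     # missing genotype
        a1[k, l] <- decode(c1, loci[l])
        a2[k, l] <- decode(c2, loci[l])
      }
    }
    # recover site/year from ids like SITE_YEAR_001
    m <- regmatches(ids[1L], regexec("^(.*)_([0-9]{4})_[0-9]+$", ids[1L]))[[1L]]
    if (length(m) == 3L) {
      site <- m[2L]; year <- as.integer(m[3L])
    } else {
      site <- paste0("pop", b); year <- b
    }
    out[[b]] <- genotype_sample(site, year, a1, a2,
                                ifelse(loci %in% cand_loci,
                                       "candidate", "microsatellite"))
  }
  out
}
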
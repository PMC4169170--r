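PANEL_COLUMNS <- c("strain", "ploidy", "phenotype", "replicate_type",
                   "replicate_id", "value", "ordinal_score")

#' Validate a long-format phenotype panel
#'
#' A phenotype panel is a data frame with one row per replicate measurement:
#' columns `strain`, `ploidy` (haploid/diploid/cured), `phenotype`,
#' `replicate_type` (technical/biological), `replicate_id`, `value`
#' (nonnegative quantitative value, may be `NA`) and `ordinal_score`
#' (integer 0-5, may be `NA`). An optional `niche` column carries the origin
#' label. Keys `(strain, ploidy, phenotype, replicate_type, replicate_id)`
#' must be unique.
#'
#' @param panel A data frame.
#' @return The panel, invisibly, if valid; otherwise a validation error whose
#'   message names the offending rows.
#' @export
validate_panel <- function(panel) {
  if (!is.data.frame(panel) || nrow(panel) == 0L) {
    abort_validation("panel must be a non-empty data frame")
  }
  missing_cols <- setdiff(PANEL_COLUMNS, names(panel))
  if (length(missing_cols)) {
    abort_validation("panel is missing columns: %s",
                     paste(missing_cols, collapse = ", "))
  }
  bad_ploidy <- which(!panel$ploidy %in% c("haploid", "diploid", "cured"))
  if (length(bad_ploidy)) {
    abort_validation("invalid ploidy at rows: %s",
                     paste(utils::head(bad_ploidy, 5), collapse = ", "))
  }
  bad_rt <- which(!panel$replicate_type %in% c("technical", "biological"))
  if (length(bad_rt)) {
    abort_validation("invalid replicate_type at rows: %s",
                     paste(utils::head(bad_rt, 5), collapse = ", "))
  }
  sc <- panel$ordinal_score
  bad_score <- which(!is.na(sc) & (sc < 0 | sc > 5 | sc != round(sc)))
  if (length(bad_score)) {
    abort_validation("ordinal_score outside {0,...,5} at rows: %s",
                     paste(utils::head(bad_score, 5), collapse = ", "))
  }
  bad_val <- which(!is.na(panel$value) & panel$value < 0 &
                     panel$phenotype %in% c("flocculation", "invasion", "adhesion"))
  if (length(bad_val)) {
    abort_validation("negative quantitative value at rows: %s",
                     paste(utils::head(bad_val, 5), collapse = ", "))
  }
  key <- do.call(paste, c(panel[c("strain", "ploidy", "phenotype",
                                  "replicate_type", "replicate_id")],
                          sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort_validation("duplicated (strain, ploidy, phenotype, replicate) rows: %s",
                     paste(utils::head(dup, 5), collapse = ", "))
  }
  invisible(panel)
}

#' Read or write a phenotype panel CSV/TSV
#'
#' The on-disk format is the long format of [validate_panel()]; the delimiter
#' is inferred from the file extension (`.tsv` tab, otherwise comma).
#'
#' @param path File path.
#' @return `read_panel()` returns the validated panel data frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort_validation("panel file not found: %s", path)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  panel <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  validate_panel(panel)
  panel
}

#' @rdname read_panel
#' @param panel A valid phenotype panel.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(panel, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Crystal-violet adhesion score from OD570 well readings
#'
#' Averages the absorbance at 570 nm of the solubilized crystal violet over
#' the technical replicate wells (two to three per strain). An optional blank
#' is subtracted from each well first; readings that fall below zero after
#' subtraction (or arrive negative) are clamped at zero with a warning.
#'
#' @param wells Numeric OD570 readings.
#' @param blank Optional blank absorbance subtracted per well (default 0).
#' @return An `adhesion_measurement`: list with `per_well_od570` (after blank
#'   subtraction and clamping) and their mean `score`.
#' @examples
#' adhesion_score(c(0.5, 0.7))$score  # 0.6
#' @export
adhesion_score <- function(wells, blank = 0) {
  if (length(wells) == 0L) abort_validation("at least one well reading required")
  if (!is.numeric(wells) || anyNA(wells)) {
    abort_validation("well readings must be numeric and non-missing")
  }
  check_scalar(blank, "blank", lower = 0)
  adj <- wells - blank
  if (any(adj < 0)) {
    warning("negative OD570 after blank subtraction; clamped to 0", call. = FALSE)
    adj <- pmax(adj, 0)
  }
  structure(list(per_well_od570 = adj, score = mean(adj)),
            class = "adhesion_measurement")
}

#' Linearly normalize values to the 0-5 scale
#'
#' Maps per-strain quantitative values for one phenotype onto the ordinal
#' scoring scale: `x -> 5 * (x - min) / (max - min)`, so the weakest strain
#' maps to 0 and the strongest to 5. A constant vector maps entirely to 0
#' (no signal to spread). This is the transform applied per phenotype before
#' clustering strains.
#'
#' @param values Numeric vector (`NA` allowed; preserved).
#' @return Values on \[0, 5\].
#' @examples
#' linear_normalize(c(0, 2, 4))  # 0 2.5 5
#' @export
linear_normalize <- function(values) {
  if (length(values) == 0L) abort_validation("no values to normalize")
  rng <- range(values, na.rm = TRUE)
  if (!all(is.finite(rng))) abort_validation("values contain no finite entries")
  if (rng[1] == rng[2]) return(ifelse(is.na(values), NA_real_, 0))
  5 * (values - rng[1]) / (rng[2] - rng[1])
}

#' Bin quantitative values into k equal-width levels
#'
#' Divides the observed range \[min, max\] into `k` equal-width bins and
#' returns integer bin indices 1..k (the maximum falls in bin `k`). Used to
#' map quantitative data onto the 5-level color-intensity scale of the
#' phenotype displays. A constant vector is all bin 1.
#'
#' @param values Numeric vector.
#' @param k Number of bins (default 5).
#' @return Integer bins in 1..k.
#' @export
bin_quantitative <- function(values, k = 5) {
  if (length(values) == 0L) abort_validation("no values to bin")
  check_count(k, "k", lower = 2L)
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    return(ifelse(is.na(values), NA_integer_, 1L))
  }
  b <- floor((values - rng[1]) / (rng[2] - rng[1]) * k) + 1L
  as.integer(pmin(b, k))
}

#' Mean quantitative value per ordinal score level
#'
#' Groups per-strain quantitative values by the strains' ordinal 0-5 scores
#' and reports the mean and count per level, the summary used to relate a
#' quantitative assay to colony-complexity grades. Levels with no strains are
#' reported with `NA` mean and count 0.
#'
#' @param quantitative Named or unnamed numeric vector, one value per strain.
#' @param scores Ordinal scores (0-5), aligned with `quantitative`.
#' @return Data frame with columns `score`, `mean_value`, `n`.
#' @export
group_by_score <- function(quantitative, scores) {
  if (length(quantitative) != length(scores)) {
    abort_validation("quantitative values and scores must align (got %d vs %d)",
                     length(quantitative), length(scores))
  }
  if (!is.null(names(quantitative)) && !is.null(names(scores)) &&
      !identical(sort(names(quantitative)), sort(names(scores)))) {
    abort_validation("strain sets of values and scores differ")
  }
  if (!is.null(names(quantitative)) && !is.null(names(scores))) {
    scores <- scores[names(quantitative)]
  }
  lev <- 0:5
  means <- vapply(lev, function(s) {
    v <- quantitative[!is.na(scores) & scores == s]
    if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  }, numeric(1))
  counts <- vapply(lev, function(s) sum(!is.na(scores) & scores == s), integer(1))
  data.frame(score = lev, mean_value = means, n = counts)
}

#' Collapse a replicate level of a panel by averaging
#'
#' Averages the quantitative values of the requested replicate level
#' (technical or biological) within each (strain, ploidy, phenotype) stratum;
#' missing replicate values are dropped from the mean. Ordinal scores are
#' averaged and rounded to the nearest integer level. Rows of the other
#' replicate level pass through unchanged.
#'
#' @param panel A valid phenotype panel.
#' @param level `"technical"` or `"biological"`.
#' @return A phenotype panel with one row per stratum at the collapsed level.
#' @export
aggregate_replicates <- function(panel, level = c("technical", "biological")) {
  level <- match.arg(level)
  validate_panel(panel)
  sel <- panel$replicate_type == level
  if (!any(sel)) {
    abort_validation("panel has no '%s' replicates", level)
  }
  sub <- panel[sel, , drop = FALSE]
  key <- interaction(sub$strain, sub$ploidy, sub$phenotype, drop = TRUE,
                     sep = "\r")
  first <- !duplicated(key)
  out <- sub[first, , drop = FALSE]
  out$value <- as.numeric(tapply(sub$value, key, mean, na.rm = TRUE))[
    match(key[first], levels(key))]
  osc <- tapply(sub$ordinal_score, key, function(s) {
    s <- s[!is.na(s)]
    if (length(s)) as.integer(round(mean(s))) else NA_integer_
  })
  out$ordinal_score <- as.integer(osc)[match(key[first], levels(key))]
  out$replicate_id <- 1L
  out$value[is.nan(out$value)] <- NA_real_
  rownames(out) <- NULL
  rbind(out, panel[!sel, , drop = FALSE])
}
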
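#' Remove duplicate and invalid rows
#'
#' Exact-duplicate rows (all feature columns equal, missing matching
#' missing) are reduced to their first occurrence. Rows carrying an
#' unparseable cell or any continuous value outside its schema
#' `valid_range` are dropped as invalid. A row that is both a duplicate
#' and invalid counts once, as a duplicate. The operation is idempotent.
#'
#' @param x A `cohort_table`.
#' @return A list with elements `cohort` (the cleaned `cohort_table`) and
#'   `report` (a `preprocess_report`).
#' @export
remove_duplicates_and_invalid <- function(x) {
  n_raw <- n_cohort_rows(x)
  dup <- duplicated(as.data.frame(x$data))

  out_of_range <- rep(FALSE, n_raw)
  cont <- x$schema[x$schema$kind == "continuous", , drop = FALSE]
  for (i in seq_len(nrow(cont))) {
    v <- x$data[[cont$name[i]]]
    lo <- cont$lower[i]; hi <- cont$upper[i]
    if (!is.na(lo)) out_of_range <- out_of_range | (!is.na(v) & v < lo)
    if (!is.na(hi)) out_of_range <- out_of_range | (!is.na(v) & v > hi)
  }
  if (nrow(x$invalid)) out_of_range[unique(x$invalid$row)] <- TRUE

  invalid <- out_of_range & !dup
  keep <- !dup & !invalid
  cleaned <- subset_rows(x, which(keep))
  report <- preprocess_report(cleaned,
                              n_raw = n_raw,
                              n_duplicates_removed = sum(dup),
                              n_invalid_removed = sum(invalid))
  list(cohort = cleaned, report = report)
}

#' Preprocessing report
#'
#' Bookkeeping for the cleaning stage: raw/removed/retained row counts,
#' per-column missing-value counts (the "data brief" shape), the number of
#' rows with any missing value, and outcome class counts if labelled.
#'
#' @param x The retained `cohort_table`.
#' @param n_raw,n_duplicates_removed,n_invalid_removed Row counts.
#' @return A `preprocess_report` object.
#' @export
preprocess_report <- function(x, n_raw,
                              n_duplicates_removed = 0L,
                              n_invalid_removed = 0L) {
  n_retained <- n_cohort_rows(x)
  stopifnot(n_raw == n_duplicates_removed + n_invalid_removed + n_retained)
  miss <- vapply(x$data, function(v) sum(is.na(v)), integer(1))
  structure(list(
    n_raw = n_raw,
    n_duplicates_removed = as.integer(n_duplicates_removed),
    n_invalid_removed = as.integer(n_invalid_removed),
    n_retained = n_retained,
    missing_by_column = miss[miss > 0L],
    missing_rows = sum(rowSums(is.na(x$data)) > 0L),
    class_counts = if (!is.null(x$outcome)) table(x$outcome)
  ), class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocessing report\n")
  cat(sprintf("  rows: %d raw = %d duplicates + %d invalid + %d retained\n",
              x$n_raw, x$n_duplicates_removed, x$n_invalid_removed,
              x$n_retained))
  if (length(x$missing_by_column)) {
    cat("  missing values by column:\n")
    for (nm in names(x$missing_by_column)) {
      cat(sprintf("    %-28s %d\n", nm, x$missing_by_column[[nm]]))
    }
    cat(sprintf("  %d rows with missing values, %d missing cells total\n",
                x$missing_rows, sum(x$missing_by_column)))
  } else {
    cat("  no missing values\n")
  }
  if (!is.null(x$class_counts)) {
    pct <- 100 * x$class_counts / sum(x$class_counts)
    cat("  classes: ",
        paste(sprintf("%s=%d (%.2f%%)", names(x$class_counts),
                      as.integer(x$class_counts), pct), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Median imputation of continuous columns
#'
#' `fit_impute()` learns per-column medians from the non-missing cells of
#' `fit_rows` only (so a model fitted on training rows can be applied to
#' test rows without leakage); `apply_impute()` fills every missing
#' continuous cell with the fitted median and leaves observed cells
#' untouched.
#'
#' @param x A `cohort_table`.
#' @param fit_rows Integer row indices to fit on (default: all rows).
#' @return `fit_impute()`: an `imputation_model`;
#'   `apply_impute()`: a `cohort_table` with no missing continuous cells.
#' @export
fit_impute <- function(x, fit_rows = seq_len(n_cohort_rows(x))) {
  if (!length(fit_rows)) stop("fit_rows must be non-empty", call. = FALSE)
  cols <- continuous_columns(x$schema)
  medians <- vapply(cols, function(nm) {
    v <- x$data[[nm]][fit_rows]
    v <- v[!is.na(v)]
    if (!length(v)) {
      stop("column entirely missing in fit rows: ", nm, call. = FALSE)
    }
    stats::median(v)
  }, double(1))
  structure(list(medians = medians, fitted_on = as.integer(fit_rows)),
            class = "imputation_model")
}

#' @rdname fit_impute
#' @param model An `imputation_model`.
#' @export
apply_impute <- function(model, x) {
  data <- x$data
  for (nm in names(model$medians)) {
    if (!nm %in% names(data)) next
    miss <- is.na(data[[nm]])
    if (any(miss)) data[[nm]][miss] <- model$medians[[nm]]
  }
  cohort_table(data, x$schema, outcome = x$outcome, invalid = x$invalid,
               enc = x$enc)
}

#' Standardization of continuous columns
#'
#' `fit_scaler()` learns per-column center (mean) and scale (population
#' standard deviation, i.e. divisor `n`) on `fit_rows`; `apply_scaler()`
#' transforms continuous columns to `(x - center) / scale`. Binary columns
#' are untouched. A constant column gets its scale clamped to 1 so it is
#' centred to zero rather than dividing by zero.
#'
#' @param x A `cohort_table` with no missing continuous values.
#' @param fit_rows Integer row indices to fit on.
#' @return `fit_scaler()`: a `scaler_model`; `apply_scaler()`: a scaled
#'   `cohort_table`.
#' @export
fit_scaler <- function(x, fit_rows = seq_len(n_cohort_rows(x))) {
  cols <- continuous_columns(x$schema)
  if (anyNA(x$data[fit_rows, cols])) {
    stop("scaler requires imputed data (missing values present)",
         call. = FALSE)
  }
  center <- vapply(cols, function(nm) mean(x$data[[nm]][fit_rows]), double(1))
  scale <- vapply(cols, function(nm) {
    v <- x$data[[nm]][fit_rows]
    s <- sqrt(mean((v - mean(v))^2))
    if (s <= 0) 1 else s
  }, double(1))
  structure(list(center = center, scale = scale), class = "scaler_model")
}

#' @rdname fit_scaler
#' @param model A `scaler_model`.
#' @export
apply_scaler <- function(model, x) {
  data <- x$data
  for (nm in names(model$center)) {
    if (!nm %in% names(data)) next
    data[[nm]] <- (data[[nm]] - model$center[[nm]]) / model$scale[[nm]]
  }
  cohort_table(data, x$schema, outcome = x$outcome, invalid = x$invalid,
               enc = x$enc)
}
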
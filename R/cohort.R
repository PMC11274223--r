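#' Cohort table: the package's universal data container
#'
#' A `cohort_table` couples a feature tibble with its schema, an optional
#' three-level outcome (`SGA`, `AGA`, `LGA`), and a record of cells whose
#' raw text could not be parsed (tracked separately from missing cells so
#' preprocessing can report both).
#'
#' @param data Tibble/data.frame of feature columns matching `schema$name`
#'   exactly, in order. Missing values are `NA`.
#' @param schema A [cohort_schema()].
#' @param outcome Optional factor/character vector of per-row labels in
#'   `levels(enc)`; length `nrow(data)`.
#' @param invalid Optional tibble with integer `row` and character `column`
#'   flagging unparseable cells (which are stored as `NA` in `data`).
#' @param enc Class encoding from [class_encoding()].
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(data, schema, outcome = NULL, invalid = NULL,
                         enc = class_encoding()) {
  validate_schema(schema)
  data <- tibble::as_tibble(data)
  if (!identical(names(data), schema$name)) {
    stop("data columns must match schema names exactly (same order); ",
         "mismatch starts at: ",
         paste(utils::head(setdiff(union(names(data), schema$name),
                                   intersect(names(data), schema$name)), 3),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(outcome)) {
    outcome <- as.character(outcome)
    bad <- setdiff(unique(outcome), names(enc$codes))
    if (length(bad)) {
      stop("outcome contains label(s) outside the encoding: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (length(outcome) != nrow(data)) {
      stop("outcome length != number of rows", call. = FALSE)
    }
    outcome <- factor(outcome, levels = names(enc$codes))
  }
  if (is.null(invalid)) {
    invalid <- tibble::tibble(row = integer(), column = character())
  }
  structure(
    list(data = data, schema = schema, outcome = outcome,
         invalid = tibble::as_tibble(invalid), enc = enc),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$data), " rows x ", ncol(x$data),
      " feature columns\n", sep = "")
  if (!is.null(x$outcome)) {
    tab <- table(x$outcome)
    cat("  outcome: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  outcome: <absent>\n")
  }
  nmiss <- sum(is.na(x$data))
  cat("  missing cells: ", nmiss,
      "; flagged invalid cells: ", nrow(x$invalid), "\n", sep = "")
  invisible(x)
}

#' Accessors for cohort tables
#'
#' @param x A `cohort_table`.
#' @return `cohort_data()` the feature tibble; `cohort_outcome()` the
#'   outcome factor (or `NULL`); `schema_of()` the schema;
#'   `n_cohort_rows()` the row count.
#' @export
cohort_data <- function(x) x$data

#' @rdname cohort_data
#' @export
cohort_outcome <- function(x) x$outcome

#' @rdname cohort_data
#' @export
schema_of <- function(x) x$schema

#' @rdname cohort_data
#' @export
n_cohort_rows <- function(x) nrow(x$data)

#' Subset rows or select feature columns of a cohort
#'
#' @param x A `cohort_table`.
#' @param rows Integer or logical row index.
#' @return A `cohort_table`.
#' @export
subset_rows <- function(x, rows) {
  if (is.logical(rows)) rows <- which(rows)
  if (length(rows) && all(rows < 0)) {
    rows <- setdiff(seq_len(n_cohort_rows(x)), -rows)
  }
  keep_inv <- x$invalid[x$invalid$row %in% rows, , drop = FALSE]
  keep_inv$row <- match(keep_inv$row, rows)
  cohort_table(x$data[rows, , drop = FALSE], x$schema,
               outcome = if (!is.null(x$outcome)) x$outcome[rows],
               invalid = keep_inv, enc = x$enc)
}

#' @rdname subset_rows
#' @param features Character vector of column names to keep.
#' @export
select_features <- function(x, features) {
  missing_cols <- setdiff(features, names(x$data))
  if (length(missing_cols)) {
    stop("unknown feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  schema <- x$schema[match(features, x$schema$name), , drop = FALSE]
  cohort_table(x$data[, features, drop = FALSE], schema,
               outcome = x$outcome,
               invalid = x$invalid[x$invalid$column %in% features, ,
                                   drop = FALSE],
               enc = x$enc)
}

#' Numeric feature matrix of a cohort
#'
#' Continuous and binary columns are returned as a numeric matrix in schema
#' order; categorical columns are not representable and raise an error
#' (recode them upstream).
#'
#' @param x A `cohort_table`.
#' @param features Optional subset of column names.
#' @return Numeric matrix, `n_cohort_rows(x)` by `length(features)`.
#' @export
feature_matrix <- function(x, features = NULL) {
  features <- features %||% x$schema$name
  kinds <- x$schema$kind[match(features, x$schema$name)]
  if (any(kinds == "categorical")) {
    stop("categorical column(s) cannot enter the numeric feature matrix: ",
         paste(features[kinds == "categorical"], collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(x$data[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Read a cohort CSV against a schema
#'
#' The file must have a header row matching the schema names (CSV,
#' UTF-8, empty string = missing). Cells in continuous/binary columns that
#' are non-empty but unparseable as numbers are flagged *invalid* (stored
#' as `NA` and recorded in the `invalid` slot), distinct from missing.
#'
#' @param path CSV file path.
#' @param schema A [cohort_schema()].
#' @param outcome_col Optional name of a label column in the file (not part
#'   of the schema) holding `SGA`/`AGA`/`LGA` labels.
#' @param enc Class encoding.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, schema, outcome_col = NULL,
                        enc = class_encoding()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    name_repair = "minimal")
  if (anyDuplicated(names(raw))) {
    stop("duplicated header name(s): ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  }
  expected <- c(schema$name, outcome_col)
  unknown <- setdiff(names(raw), expected)
  absent <- setdiff(expected, names(raw))
  if (length(unknown) || length(absent)) {
    stop("header does not match schema",
         if (length(unknown)) paste0("; unknown: ",
                                     paste(unknown, collapse = ", ")),
         if (length(absent)) paste0("; absent: ",
                                    paste(absent, collapse = ", ")),
         call. = FALSE)
  }
  invalid <- list()
  parsed <- lapply(seq_len(nrow(schema)), function(i) {
    nm <- schema$name[i]
    txt <- raw[[nm]]
    if (schema$kind[i] == "categorical") return(txt)
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & nzchar(txt) & is.na(val))
    if (length(bad)) {
      invalid[[nm]] <<- tibble::tibble(row = as.integer(bad), column = nm)
    }
    val
  })
  names(parsed) <- schema$name
  invalid <- if (length(invalid)) dplyr::bind_rows(invalid) else NULL
  outcome <- if (!is.null(outcome_col)) raw[[outcome_col]]
  cohort_table(tibble::as_tibble(parsed), schema,
               outcome = outcome, invalid = invalid, enc = enc)
}

#' Write a cohort to CSV
#'
#' Missing cells are written as empty strings; doubles are written with
#' round-trip precision. If an outcome is present it is written as a
#' trailing `InfantType` column.
#'
#' @param x A `cohort_table`.
#' @param path Output path.
#' @param outcome_col Name for the label column when outcome is present.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, outcome_col = "InfantType") {
  out <- x$data
  if (!is.null(x$outcome)) out[[outcome_col]] <- as.character(x$outcome)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Merge raw SGA/LGA indicator columns into the three-level outcome
#'
#' Rows with the small-for-gestational-age indicator set become `SGA`,
#' rows with the large-for-gestational-age indicator set become `LGA`,
#' and all remaining rows `AGA`. The two indicator columns are removed
#' from the feature table. A row with both indicators set is a labelling
#' conflict and raises an error listing the offending row indices.
#'
#' @param x A `cohort_table` without an outcome.
#' @param sga_col,lga_col Names of the 0/1 indicator columns.
#' @return A `cohort_table` with `outcome` set and indicators dropped.
#' @export
build_outcome <- function(x, sga_col = "sga", lga_col = "lga") {
  for (col in c(sga_col, lga_col)) {
    if (!col %in% names(x$data)) {
      stop("indicator column not found: ", col, call. = FALSE)
    }
  }
  s <- x$data[[sga_col]]
  l <- x$data[[lga_col]]
  ok <- function(v) all(v %in% c(0, 1), na.rm = TRUE) && !anyNA(v)
  if (!ok(s) || !ok(l)) {
    stop("indicator columns must be 0/1 with no missing values",
         call. = FALSE)
  }
  both <- which(s == 1 & l == 1)
  if (length(both)) {
    stop("row(s) flagged both SGA and LGA: ",
         paste(utils::head(both, 20), collapse = ", "), call. = FALSE)
  }
  outcome <- ifelse(s == 1, "SGA", ifelse(l == 1, "LGA", "AGA"))
  keep <- setdiff(names(x$data), c(sga_col, lga_col))
  schema <- x$schema[x$schema$name %in% keep, , drop = FALSE]
  cohort_table(x$data[, keep, drop = FALSE], schema,
               outcome = outcome,
               invalid = x$invalid[x$invalid$column %in% keep, , drop = FALSE],
               enc = x$enc)
}

#' Class encoding between labels and integer codes
#'
#' A bijection between the three outcome labels and integer codes; the
#' default is alphabetical (`AGA = 0`, `LGA = 1`, `SGA = 2`), matching the
#' default behaviour of common machine-learning toolchains. The code order
#' also fixes the class-column order of probability blocks and the
#' tie-break order of voting.
#'
#' @param labels Character vector of labels in code order (code `0` first).
#' @return A `class_encoding` object.
#' @export
class_encoding <- function(labels = c("AGA", "LGA", "SGA")) {
  labels <- as.character(labels)
  if (anyDuplicated(labels) || anyNA(labels)) {
    stop("encoding labels must be unique and non-missing", call. = FALSE)
  }
  codes <- stats::setNames(seq_along(labels) - 1L, labels)
  structure(list(codes = codes, labels = labels), class = "class_encoding")
}

#' Encode / decode outcome labels as integers
#'
#' @param outcome Character or factor vector of labels.
#' @param enc A [class_encoding()].
#' @return `encode_labels()`: integer vector of codes;
#'   `decode_labels()`: factor of labels restoring the input exactly.
#' @export
encode_labels <- function(outcome, enc = class_encoding()) {
  outcome <- as.character(outcome)
  unseen <- setdiff(unique(outcome), enc$labels)
  if (length(unseen)) {
    stop("label(s) outside the encoding: ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  unname(enc$codes[outcome])
}

#' @rdname encode_labels
#' @param codes Integer vector of codes.
#' @export
decode_labels <- function(codes, enc = class_encoding()) {
  bad <- setdiff(unique(codes), enc$codes)
  if (length(bad)) {
    stop("code(s) outside the encoding: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(enc$labels[codes + 1L], levels = enc$labels)
}
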
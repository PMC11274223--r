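#' Column metadata for a cohort schema
#'
#' A schema describes every column of a cohort table: its measurement kind,
#' an optional closed validity interval for continuous columns (used by
#' [remove_duplicates_and_invalid()] to drop out-of-range rows), and the
#' attribute group it belongs to.
#'
#' @param name Column name (unique within a schema).
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param lower,upper Optional closed validity interval for continuous
#'   columns. `NA` means unchecked.
#' @param group Attribute group, e.g. `"common-maternal"`,
#'   `"maternal-history"`, `"current-maternal"`, `"fetal"`, `"infant"`.
#' @return A one-row tibble of column metadata.
#' @export
#' @examples
#' column_meta("age", "continuous", lower = 14, upper = 55,
#'             group = "common-maternal")
column_meta <- function(name,
                        kind = c("continuous", "binary", "categorical"),
                        lower = NA_real_, upper = NA_real_,
                        group = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  lower <- as.double(lower)
  upper <- as.double(upper)
  if (!is.na(lower) && !is.na(upper) && lower > upper) {
    stop("valid_range for column '", name, "' has lower > upper", call. = FALSE)
  }
  tibble::tibble(name = name, kind = kind,
                 lower = lower, upper = upper, group = as.character(group))
}

#' Assemble and validate a cohort schema
#'
#' @param ... One-row tibbles from [column_meta()], or data frames of them.
#' @return A `cohort_schema` tibble with columns
#'   `name`, `kind`, `lower`, `upper`, `group`.
#' @export
cohort_schema <- function(...) {
  schema <- dplyr::bind_rows(...)
  validate_schema(schema)
  class(schema) <- c("cohort_schema", class(schema))
  schema
}

validate_schema <- function(schema) {
  required <- c("name", "kind", "lower", "upper", "group")
  missing_cols <- setdiff(required, names(schema))
  if (length(missing_cols)) {
    stop("schema lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(schema$name)) {
    dup <- unique(schema$name[duplicated(schema$name)])
    stop("duplicate column name(s) in schema: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(schema$kind),
                      c("continuous", "binary", "categorical"))
  if (length(bad_kind)) {
    stop("unknown column kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  bad_range <- !is.na(schema$lower) & !is.na(schema$upper) &
    schema$lower > schema$upper
  if (any(bad_range)) {
    stop("valid_range has lower > upper for: ",
         paste(schema$name[bad_range], collapse = ", "), call. = FALSE)
  }
  invisible(schema)
}

#' Default schema for a first-trimester SGA/LGA/AGA cohort
#'
#' Reconstructs a 34-column raw cohort layout: maternal demographics,
#' maternal-history flags, current-pregnancy measurements and biomarkers
#' (fasting plasma glucose, lipid panel, oral glucose tolerance test),
#' fetal attributes, and the raw `sga`/`lga` outcome indicator columns
#' that [build_outcome()] merges into the three-level label. Validity
#' ranges are broad clinical-plausibility bounds used to flag
#' invalid-entry rows.
#'
#' @return A `cohort_schema` tibble with 34 rows.
#' @export
sga_lga_schema <- function() {
  cm <- column_meta
  cohort_schema(
    cm("age",                        "continuous", 14, 55,   "common-maternal"),
    cm("height",                     "continuous", 1.2, 2.2, "common-maternal"),
    cm("prepregnancy_weight",        "continuous", 30, 150,  "common-maternal"),
    cm("education_time",             "continuous", 0, 30,    "maternal-history"),
    cm("diabetes_family_history",    "binary", group = "maternal-history"),
    cm("gdm_history",                "binary", group = "maternal-history"),
    cm("birthing_lga_baby",          "binary", group = "maternal-history"),
    cm("parous",                     "binary", group = "maternal-history"),
    cm("postpregnancy_weight",       "continuous", 30, 200,  "current-maternal"),
    cm("weight_change",              "continuous", -20, 40,  "current-maternal"),
    cm("pre_bmi",                    "continuous", 12, 50,   "current-maternal"),
    cm("premature_membrane_rupture", "binary", group = "current-maternal"),
    cm("placental_abruption",        "binary", group = "current-maternal"),
    cm("gestational_hypertension",   "binary", group = "current-maternal"),
    cm("pre_eclampsia",              "binary", group = "current-maternal"),
    cm("placenta_previa",            "binary", group = "current-maternal"),
    cm("polyhydramnios",             "binary", group = "current-maternal"),
    cm("oligohydramnios",            "binary", group = "current-maternal"),
    cm("postpartum_bleeding_volume", "continuous", 0, 5000,  "current-maternal"),
    cm("postpartum_bleeding",        "binary", group = "current-maternal"),
    cm("fpg",                        "continuous", 1, 15,    "current-maternal"),
    cm("tc",                         "continuous", 0.5, 20,  "current-maternal"),
    cm("tg",                         "continuous", 0.1, 20,  "current-maternal"),
    cm("hdl",                        "continuous", 0.1, 6,   "current-maternal"),
    cm("ldl",                        "continuous", 0.1, 15,  "current-maternal"),
    cm("tyg_index",                  "continuous", 5, 12,    "current-maternal"),
    cm("ogtt_0h",                    "continuous", 1, 15,    "current-maternal"),
    cm("ogtt_1h",                    "continuous", 1, 25,    "current-maternal"),
    cm("ogtt_2h",                    "continuous", 1, 25,    "current-maternal"),
    cm("infant_gender",              "binary", group = "fetal"),
    cm("fetal_growth_restriction",   "binary", group = "fetal"),
    cm("birth_weight",               "continuous", 300, 6500, "infant"),
    cm("sga",                        "binary", group = "infant"),
    cm("lga",                        "binary", group = "infant")
  )
}

#' Read / write a schema as a YAML config file
#'
#' The file holds a top-level `columns:` list; each entry declares `name`,
#' `kind`, optional `range: [lower, upper]`, and optional `group`.
#'
#' @param path File path.
#' @return `read_schema()` returns a `cohort_schema`;
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$columns)) stop("schema file has no 'columns' entry", call. = FALSE)
  rows <- lapply(cfg$columns, function(col) {
    rng <- col$range %||% c(NA_real_, NA_real_)
    column_meta(col$name, col$kind %||% "continuous",
                lower = rng[[1]], upper = rng[[2]],
                group = col$group %||% NA_character_)
  })
  do.call(cohort_schema, rows)
}

#' @rdname read_schema
#' @param schema A `cohort_schema`.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  cols <- lapply(seq_len(nrow(schema)), function(i) {
    entry <- list(name = schema$name[i], kind = schema$kind[i])
    if (!is.na(schema$lower[i]) || !is.na(schema$upper[i])) {
      entry$range <- c(schema$lower[i], schema$upper[i])
    }
    if (!is.na(schema$group[i])) entry$group <- schema$group[i]
    entry
  })
  yaml::write_yaml(list(columns = cols), path)
  invisible(path)
}

continuous_columns <- function(schema) schema$name[schema$kind == "continuous"]
binary_columns     <- function(schema) schema$name[schema$kind == "binary"]

`%||%` <- function(x, y) if (is.null(x)) y else x
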
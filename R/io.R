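# Cohort CSV schema: column name -> expected type.
cohort_schema <- c(
  patient_id = "character", tumor_id = "character", age_years = "numeric",
  sex = "character", location = "character", gtv_cc = "numeric",
  ptv_cc = "numeric", bmi = "numeric", n_fractions = "integer",
  dose_per_fraction_gy = "numeric", ptbe_event = "integer",
  time_to_event_days = "numeric", hypertension = "integer",
  diabetes = "integer"
)

#' Cohort CSV column names
#'
#' The documented per-tumor cohort schema shared by [read_cohort()],
#' [write_cohort()] and [generate_cohort()].
#'
#' @return Character vector of the 14 required column names, in order.
#' @export
cohort_columns <- function() names(cohort_schema)

#' Read a cohort CSV
#'
#' Reads and validates a per-tumor cohort table. Every schema violation is
#' collected and reported at once, with 1-based data row numbers: missing
#' columns, non-numeric values in numeric columns, non-positive doses or
#' fraction counts, non-positive follow-up times, and indicator columns
#' (`ptbe_event`, `hypertension`, `diabetes`) outside \{0, 1\}.
#'
#' @param path Path to a UTF-8 CSV file with the header of
#'   [cohort_columns()], one row per tumor.
#' @return A validated tibble with typed columns.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      "Cohort file is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  problems <- character()
  note <- function(rows, col, vals) {
    problems <<- c(problems, sprintf("row %d: %s = '%s'", rows, col, vals))
  }
  numeric_cols <- names(cohort_schema)[cohort_schema %in% c("numeric", "integer")]
  parsed <- raw
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) note(bad, col, raw[[col]][bad])
    parsed[[col]] <- v
  }
  check_rule <- function(col, ok) {
    bad <- which(!is.na(parsed[[col]]) & !ok)
    if (length(bad) > 0) note(bad, col, raw[[col]][bad])
  }
  check_rule("dose_per_fraction_gy", parsed$dose_per_fraction_gy > 0)
  check_rule("n_fractions", parsed$n_fractions >= 1 &
    parsed$n_fractions == floor(parsed$n_fractions))
  check_rule("time_to_event_days", parsed$time_to_event_days > 0)
  for (col in c("ptbe_event", "hypertension", "diabetes")) {
    check_rule(col, parsed[[col]] %in% c(0, 1))
  }
  if (length(problems) > 0) {
    stop_schema(paste0(
      "Cohort file failed validation:\n",
      paste0("  ", problems, collapse = "\n")
    ))
  }
  for (col in names(cohort_schema)[cohort_schema == "integer"]) {
    parsed[[col]] <- as.integer(parsed[[col]])
  }
  parsed[, cohort_columns()]
}

#' Write a cohort CSV
#'
#' @param cohort A cohort tibble in the schema of [cohort_columns()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("Cohort is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(cohort[, cohort_columns()], path)
  invisible(path)
}
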
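delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_table_checked <- function(path, numeric_cols, required_cols) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "warfinr_io_error")
  }
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  missing_cols <- setdiff(required_cols, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(missing_cols, collapse = ", ")),
          class = "warfinr_schema_error")
  }
  for (col in intersect(numeric_cols, names(raw))) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad)) {
      abort(sprintf("%s: non-numeric value in column `%s` at line(s) %s (1 = first data row).",
                    path, col, paste(head(bad, 5), collapse = ", ")),
            class = "warfinr_parse_error", lines = bad, column = col)
    }
    raw[[col]] <- vals
  }
  raw
}

#' Read a visit-record table
#'
#' Reads the canonical longitudinal visit table (TSV by default, CSV by
#' extension): columns `patient_id`, `t_days`, `inr`, `dose_mg` and
#' optionally `tau_h` (filled with the once-daily default 24 when absent).
#' Rows are sorted per patient by time on load; malformed numeric cells and
#' rows violating the invariants (`t_days >= 0`, `inr > 0`, `dose_mg > 0`)
#' are rejected with their line numbers.
#'
#' @param path Path to the delimited file.
#' @return A visit tibble.
#' @export
read_visits <- function(path) {
  raw <- read_table_checked(path,
                            numeric_cols = c("t_days", "inr", "dose_mg", "tau_h"),
                            required_cols = c("patient_id", "t_days", "inr", "dose_mg"))
  if (!"tau_h" %in% names(raw)) {
    inform("No tau_h column; assuming once-daily dosing (tau_h = 24).")
    raw$tau_h <- 24
  }
  bad <- which(!is.finite(raw$t_days) | raw$t_days < 0 |
                 !is.finite(raw$inr) | raw$inr <= 0 |
                 !is.finite(raw$dose_mg) | raw$dose_mg <= 0 |
                 !is.finite(raw$tau_h) | raw$tau_h <= 0)
  if (length(bad)) {
    abort(sprintf("%s: invalid visit row(s) at line(s) %s (t_days >= 0, inr > 0, dose_mg > 0, tau_h > 0 required).",
                  path, paste(head(bad, 5), collapse = ", ")),
          class = "warfinr_parse_error", lines = bad)
  }
  raw <- raw[order(raw$patient_id, raw$t_days), ]
  tibble::as_tibble(raw[c("patient_id", "t_days", "inr", "dose_mg", "tau_h")])
}

#' Read a demographics table
#'
#' Columns: `patient_id`, `age_years`, `sex` (M/F), `body_weight_kg`,
#' `interacting_drug` (0/1). One row per patient.
#'
#' @param path Path to the delimited file.
#' @return A demographics tibble.
#' @export
read_demographics <- function(path) {
  raw <- read_table_checked(path,
                            numeric_cols = c("age_years", "body_weight_kg", "interacting_drug"),
                            required_cols = c("patient_id", "age_years", "sex",
                                              "body_weight_kg", "interacting_drug"))
  if (anyDuplicated(raw$patient_id)) {
    abort(sprintf("%s: duplicated patient_id(s): %s.", path,
                  paste(unique(raw$patient_id[duplicated(raw$patient_id)]), collapse = ", ")),
          class = "warfinr_schema_error")
  }
  sex_indicator(raw$sex)  # validates coding
  bad <- which(!is.finite(raw$body_weight_kg) | raw$body_weight_kg <= 0 |
                 !raw$interacting_drug %in% c(0, 1))
  if (length(bad)) {
    abort(sprintf("%s: invalid demographics row(s) at line(s) %s.",
                  path, paste(head(bad, 5), collapse = ", ")),
          class = "warfinr_parse_error", lines = bad)
  }
  tibble::as_tibble(raw[c("patient_id", "age_years", "sex", "body_weight_kg",
                          "interacting_drug")])
}

#' Read a full cohort (visits + demographics)
#'
#' @param visits_path,demographics_path Paths to the two tables.
#' @return A list of class `warfinr_cohort` with `visits` and `demographics`
#'   tibbles (no `truth` component for real data).
#' @export
read_cohort <- function(visits_path, demographics_path) {
  visits <- read_visits(visits_path)
  demographics <- read_demographics(demographics_path)
  orphans <- setdiff(unique(visits$patient_id), demographics$patient_id)
  if (length(orphans)) {
    abort(sprintf("Visit table has patient id(s) absent from demographics: %s.",
                  paste(head(orphans, 10), collapse = ", ")),
          class = "warfinr_schema_error", orphans = orphans)
  }
  structure(list(visits = visits, demographics = demographics,
                 truth = NULL, config = NULL),
            class = "warfinr_cohort")
}

#' Write a cohort's tables to a directory
#'
#' Writes `visits.tsv`, `demographics.tsv` and, when present, `truth.tsv`.
#' Output is deterministic, so re-writing an unchanged cohort is byte-stable
#' and `write_cohort()` then [read_cohort()] round-trips exactly.
#'
#' @param cohort A `warfinr_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "warfinr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$visits, file.path(dir, "visits.tsv"))
  readr::write_tsv(cohort$demographics, file.path(dir, "demographics.tsv"))
  if (!is.null(cohort$truth)) {
    readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}
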
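# Cohort CSV schema: one row per trauma admission. Enums are lowercase
# strings, missing values are empty cells. Registry severity scores (ISS,
# AIS, GCS, RTS, TRISS, SOFA) are consumed as-is; their computation from raw
# injury data is out of scope.

.cohort_columns <- c(
  "patient_id", "age", "sex", "mechanism", "hr", "sbp", "dbp", "fast",
  "lactate", "gcs", "iss", "abdominal_ais", "pelvic_ais", "rts", "triss",
  "sofa", "fibrinogen", "transfused", "blood_units", "mtp", "laparotomy",
  "management", "icu_los", "hospital_los", "mortality")

.cohort_enums <- list(
  sex = c("male", "female"),
  mechanism = c("blunt", "penetrating"),
  fast = c("negative", "positive", "indeterminate"),
  management = c("conservative", "conservative_plus_ir", "surgical",
                 "ir_only", "surgical_plus_ir"))

.cohort_logical <- c("transfused", "mtp", "laparotomy", "mortality")

#' Cohort column names
#'
#' The canonical column set of the cohort CSV schema, in order.
#' @return Character vector of column names.
#' @export
cohort_columns <- function() .cohort_columns

#' Validate a cohort data frame
#'
#' Checks column presence, enum levels, vital-sign positivity and the
#' structural invariants (massive transfusion implies >= 10 blood units;
#' logical outcome flags are logical).
#'
#' @param cohort A data frame in the cohort schema.
#' @param strict If `TRUE` (default) violations are errors; otherwise a
#'   character vector of messages is returned.
#' @return The cohort, invisibly, or a character vector of problems when
#'   `strict = FALSE`.
#' @export
validate_cohort <- function(cohort, strict = TRUE) {
  problems <- character()
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols))
    problems <- c(problems, paste("missing columns:",
                                  paste(missing_cols, collapse = ", ")))
  for (col in names(.cohort_enums)) {
    if (!col %in% names(cohort)) next
    x <- cohort[[col]]
    bad <- !is.na(x) & !(x %in% .cohort_enums[[col]])
    if (any(bad))
      problems <- c(problems, paste0("column '", col, "': invalid value(s) ",
                                     paste(unique(x[bad]), collapse = ", ")))
  }
  for (col in c("hr", "sbp", "dbp")) {
    if (!col %in% names(cohort)) next
    if (any(!is.na(cohort[[col]]) & cohort[[col]] <= 0))
      problems <- c(problems, paste0("column '", col, "': non-positive values"))
  }
  if (all(c("lactate") %in% names(cohort)) &&
      any(!is.na(cohort$lactate) & cohort$lactate < 0))
    problems <- c(problems, "column 'lactate': negative values")
  if (all(c("mtp", "blood_units") %in% names(cohort))) {
    viol <- !is.na(cohort$mtp) & cohort$mtp &
      (is.na(cohort$blood_units) | cohort$blood_units < 10)
    if (any(viol))
      problems <- c(problems,
                    "mtp = TRUE requires blood_units >= 10 (rows ",
                    paste(which(viol), collapse = ", "))
  }
  if (length(problems) && strict)
    stop("invalid cohort: ", paste(problems, collapse = "; "), call. = FALSE)
  if (strict) invisible(cohort) else problems
}

#' Read a cohort CSV
#'
#' @param path Path to a CSV in the cohort schema (header row, lowercase enum
#'   strings, empty cells for missing values).
#' @param validate Run [validate_cohort()] after parsing (default `TRUE`).
#' @return A data frame, logical outcome columns coerced to logical.
#' @export
read_cohort_csv <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  for (col in intersect(.cohort_logical, names(cohort))) {
    x <- cohort[[col]]
    if (is.character(x)) x <- tolower(x) %in% c("true", "t", "1", "yes")
    cohort[[col]] <- as.logical(x)
  }
  if (validate) validate_cohort(cohort)
  cohort
}

#' Write a cohort (or scored cohort) CSV
#'
#' Deterministic output: fixed column order, no row names, no quoting of
#' numerics. Logical columns are written as `TRUE`/`FALSE`.
#'
#' @param cohort Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Score every record of a cohort
#'
#' Appends the FASILA breakdown, risk class, ABC score and both shock
#' indices to a cohort data frame. Rows with an indeterminate FAST (or other
#' unscorable fields) are flagged in `score_flag`, never dropped.
#'
#' @param cohort Data frame in the cohort schema.
#' @param cutoff Low/high FASILA cutoff (default 4).
#' @param check_range Warn on vitals outside sanity bounds (default `TRUE`).
#' @return The cohort with appended columns `fast_points`, `si_points`,
#'   `lactate_points`, `fasila_total`, `fasila_class`, `abc_total`,
#'   `abc_mtp_predicted`, `systolic_si`, `diastolic_si`, `score_flag`.
#' @export
score_cohort <- function(cohort, cutoff = 4L, check_range = TRUE) {
  needed <- c("mechanism", "fast", "hr", "sbp", "dbp", "lactate")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns required for scoring: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  fb <- fasila_score(cohort$fast, cohort$hr, cohort$sbp, cohort$lactate,
                     indeterminate = "flag", check_range = check_range)
  ab <- abc_score(cohort$mechanism, cohort$fast, cohort$sbp, cohort$hr,
                  indeterminate = "flag")
  out <- cohort
  out$fast_points <- fb$fast_points
  out$si_points <- fb$si_points
  out$lactate_points <- fb$lactate_points
  out$fasila_total <- fb$total
  out$fasila_class <- as.character(fasila_risk_class(fb$total, cutoff))
  out$abc_total <- ab$total
  out$abc_mtp_predicted <- ab$mtp_predicted
  out$systolic_si <- systolic_shock_index(cohort$hr, cohort$sbp,
                                          check_range = FALSE)
  out$diastolic_si <- diastolic_shock_index(cohort$hr, cohort$dbp,
                                            check_range = FALSE)
  out$score_flag <- ifelse(is.na(out$fasila_total),
                           "unscorable_fast", "")
  out
}

#' Named outcome presets
#'
#' The analyses switch among several binary outcomes; these presets name
#' them. `"surgery"` means management is surgical or surgical-plus-IR (the
#' definition behind the published diagnostic panel); `"laparotomy"`,
#' `"transfusion"`, `"mtp"` and `"mortality"` map to the corresponding flags.
#'
#' @param cohort A cohort data frame.
#' @param outcome Preset name.
#' @return Logical vector, one element per row.
#' @export
outcome_vector <- function(cohort,
                           outcome = c("surgery", "laparotomy", "transfusion",
                                       "mtp", "mortality")) {
  outcome <- match.arg(outcome)
  switch(outcome,
    surgery = !is.na(cohort$management) &
      cohort$management %in% c("surgical", "surgical_plus_ir"),
    laparotomy = cohort$laparotomy %in% TRUE,
    transfusion = cohort$transfused %in% TRUE,
    mtp = cohort$mtp %in% TRUE,
    mortality = cohort$mortality %in% TRUE)
}
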
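#' Systolic shock index
#'
#' Heart rate divided by systolic blood pressure. Values above roughly 0.9
#' indicate haemodynamic compromise in adult trauma patients.
#'
#' @param hr Heart rate, beats/min. Must be positive.
#' @param sbp Systolic blood pressure, mmHg. Must be positive.
#' @param check_range If `TRUE` (default), warn when inputs fall outside
#'   physiological sanity bounds (HR 20-250, SBP 40-300) -- a common signature
#'   of unit mistakes in CSV input. The value is still computed.
#' @return Numeric vector of dimensionless ratios.
#' @examples
#' systolic_shock_index(100, 100) # 1.0
#' systolic_shock_index(90, 120)  # 0.75
#' @export
systolic_shock_index <- function(hr, sbp, check_range = TRUE) {
  check_positive(hr, "hr")
  check_positive(sbp, "sbp")
  if (check_range) warn_vital_range(hr, sbp)
  hr / sbp
}

#' Diastolic shock index
#'
#' Heart rate divided by diastolic blood pressure. The evaluation pipeline
#' uses the threshold `> 2.2` as a binary test for surgical need.
#'
#' @inheritParams systolic_shock_index
#' @param dbp Diastolic blood pressure, mmHg. Must be positive.
#' @return Numeric vector of dimensionless ratios.
#' @export
diastolic_shock_index <- function(hr, dbp, check_range = TRUE) {
  check_positive(hr, "hr")
  check_positive(dbp, "dbp")
  if (check_range) warn_vital_range(hr = hr)
  hr / dbp
}

#' Shock-index points of the FASILA score
#'
#' Bins the systolic shock index into 0-3 points: 0 below 0.70, 1 for
#' \[0.70, 0.80), 2 for \[0.80, 0.90), 3 at or above 0.90. Shock indices
#' below 0.50 (beneath the lowest published bin) score 0, the physiologically
#' least-shocked assignment, so the score is defined for all valid vitals.
#'
#' @param si Systolic shock index, must be positive.
#' @return Integer vector in 0..3.
#' @export
fasila_si_points <- function(si) {
  check_positive(si, "si")
  ifelse(si >= 0.90, 3L, ifelse(si >= 0.80, 2L, ifelse(si >= 0.70, 1L, 0L)))
}

#' Lactate points of the FASILA score
#'
#' 0 for lactate <= 2.0 mmol/L, 1 for 2.0-4.0 mmol/L (open at both shared
#' endpoints), 2 at or above 4.0 mmol/L. The explicit `<=`/`>=` qualifiers of
#' the outer bins win at the boundaries: exactly 2.0 scores 0, exactly 4.0
#' scores 2.
#'
#' @param lactate Serum lactate, mmol/L. Must be non-negative.
#' @return Integer vector in 0..2.
#' @export
fasila_lactate_points <- function(lactate) {
  if (any(!is.na(lactate) & lactate < 0))
    stop("lactate must be non-negative", call. = FALSE)
  ifelse(lactate >= 4.0, 2L, ifelse(lactate > 2.0, 1L, 0L))
}

#' FASILA score
#'
#' The FASILA score sums three bedside components measured on arrival:
#' FAST ultrasound result (negative = 0, positive = 1), systolic shock-index
#' points (0-3, [fasila_si_points()]) and serum-lactate points (0-2,
#' [fasila_lactate_points()]). The total ranges 0-6.
#'
#' @param fast Character vector: `"negative"`, `"positive"` or
#'   `"indeterminate"`.
#' @param hr,sbp Vitals at the emergency department (beats/min, mmHg).
#' @param lactate Initial serum lactate, mmol/L.
#' @param indeterminate One of `"strict"` (default; an indeterminate FAST is
#'   an error -- the score was never designed for inconclusive scans),
#'   `"negative"` or `"positive"` (score it as that result), or `"flag"`
#'   (return `NA` components for such rows; used by cohort scoring so bad rows
#'   are flagged, not dropped).
#' @param check_range Passed to [systolic_shock_index()].
#' @return A `fasila_breakdown` data frame with columns `fast_points`,
#'   `si_points`, `lactate_points`, `total`.
#' @examples
#' fasila_score("positive", hr = 90, sbp = 120, lactate = 3.0)$total # 3
#' @export
fasila_score <- function(fast, hr, sbp, lactate,
                         indeterminate = c("strict", "negative", "positive", "flag"),
                         check_range = TRUE) {
  indeterminate <- match.arg(indeterminate)
  fast <- check_enum(fast, c("negative", "positive", "indeterminate"), "fast")
  n <- max(length(fast), length(hr), length(sbp), length(lactate))
  fast <- rep_len(fast, n); hr <- rep_len(hr, n)
  sbp <- rep_len(sbp, n); lactate <- rep_len(lactate, n)

  ind <- !is.na(fast) & fast == "indeterminate"
  if (any(ind)) {
    if (indeterminate == "strict")
      stop("unscorable: FAST result is indeterminate (rows ",
           paste(which(ind), collapse = ", "),
           "); set `indeterminate` policy to score or flag them",
           call. = FALSE)
    if (indeterminate %in% c("negative", "positive"))
      fast[ind] <- indeterminate
  }

  fp <- ifelse(fast == "positive", 1L, ifelse(fast == "negative", 0L, NA_integer_))
  sp <- fasila_si_points(systolic_shock_index(hr, sbp, check_range = check_range))
  lp <- fasila_lactate_points(lactate)
  out <- data.frame(fast_points = fp, si_points = sp, lactate_points = lp,
                    total = fp + sp + lp)
  class(out) <- c("fasila_breakdown", class(out))
  out
}

#' Dichotomise a FASILA total into low/high risk
#'
#' Patients are grouped as low (< cutoff) versus high (>= cutoff) risk; the
#' published cutoff is 4.
#'
#' @param total Integer FASILA totals in 0..6 (`NA` allowed, propagated).
#' @param cutoff Risk cutoff, default 4.
#' @return Factor with levels `low`, `high`.
#' @export
fasila_risk_class <- function(total, cutoff = 4L) {
  if (any(!is.na(total) & (total < 0 | total > 6)))
    stop("FASILA total out of range 0-6", call. = FALSE)
  factor(ifelse(total >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' ABC (Assessment of Blood Consumption) score
#'
#' One point for each of: penetrating mechanism, positive FAST, SBP <= 90
#' mmHg, HR >= 120 beats/min. A total >= 2 predicts the need for massive
#' transfusion protocol activation.
#'
#' @param mechanism `"blunt"` or `"penetrating"`.
#' @param fast FAST result; see [fasila_score()] for the indeterminate policy.
#' @param sbp,hr Vitals (mmHg, beats/min), positive.
#' @param indeterminate Indeterminate-FAST policy, as in [fasila_score()].
#' @return An `abc_breakdown` data frame with the four indicator points,
#'   `total` (0-4) and `mtp_predicted` (total >= 2).
#' @export
abc_score <- function(mechanism, fast, sbp, hr,
                      indeterminate = c("strict", "negative", "positive", "flag")) {
  indeterminate <- match.arg(indeterminate)
  mechanism <- check_enum(mechanism, c("blunt", "penetrating"), "mechanism")
  fast <- check_enum(fast, c("negative", "positive", "indeterminate"), "fast")
  check_positive(sbp, "sbp"); check_positive(hr, "hr")
  n <- max(length(mechanism), length(fast), length(sbp), length(hr))
  mechanism <- rep_len(mechanism, n); fast <- rep_len(fast, n)
  sbp <- rep_len(sbp, n); hr <- rep_len(hr, n)

  ind <- !is.na(fast) & fast == "indeterminate"
  if (any(ind)) {
    if (indeterminate == "strict")
      stop("unscorable: FAST result is indeterminate (rows ",
           paste(which(ind), collapse = ", "), ")", call. = FALSE)
    if (indeterminate %in% c("negative", "positive"))
      fast[ind] <- indeterminate
  }

  fastp <- ifelse(fast == "positive", 1L,
                  ifelse(fast == "negative", 0L, NA_integer_))
  out <- data.frame(
    penetrating_point = as.integer(mechanism == "penetrating"),
    fast_point = fastp,
    sbp_point = as.integer(sbp <= 90),
    hr_point = as.integer(hr >= 120))
  out$total <- out$penetrating_point + out$fast_point + out$sbp_point + out$hr_point
  out$mtp_predicted <- out$total >= 2L
  class(out) <- c("abc_breakdown", class(out))
  out
}

# --- internal helpers -------------------------------------------------------

check_positive <- function(x, name) {
  if (any(!is.na(x) & x <= 0))
    stop(name, " must be positive", call. = FALSE)
  invisible(x)
}

check_enum <- function(x, levels, name) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    stop("invalid ", name, " value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  x
}

warn_vital_range <- function(hr = NULL, sbp = NULL) {
  if (!is.null(hr) && any(!is.na(hr) & (hr < 20 | hr > 250)))
    warning("heart rate outside sanity bounds 20-250 beats/min; check units",
            call. = FALSE)
  if (!is.null(sbp) && any(!is.na(sbp) & (sbp < 40 | sbp > 300)))
    warning("SBP outside sanity bounds 40-300 mmHg; check units",
            call. = FALSE)
  invisible(NULL)
}
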
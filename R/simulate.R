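# Seeded stochastic simulator of abdominopelvic trauma cohorts. The
# generative model is a stand-in with the statistical structure the analysis
# assumes (no generative model exists for the source registry): truncated
# normal vitals, lactate lognormal in the shock index, FAST positivity
# logistic in abdominal AIS, outcomes Bernoulli with logit linear in the
# FASILA total, severity scores positively and fibrinogen negatively coupled
# to the score.

#' Cohort simulation configuration
#'
#' Defaults emulate the published cohort's marginal structure: ~400 blunt-
#' dominant admissions (96% blunt, 90% male, age 36 +/- 13), a score
#' distribution concentrated at low values, outcome probabilities rising
#' monotonically with the score, strong positive score/shock-index coupling
#' and a mild negative fibrinogen coupling.
#'
#' @param n Cohort size (default 400).
#' @param penetrating_prob Probability of penetrating mechanism (default
#'   0.04).
#' @param male_prob Probability of male sex (default 0.90).
#' @param age_mean,age_sd,age_bounds Age model, years (truncated normal).
#' @param hr_mean,hr_sd,hr_bounds Heart-rate model, beats/min; bounds must
#'   stay within the sanity range 20-250.
#' @param sbp_mean,sbp_sd,sbp_bounds Systolic pressure model, mmHg; bounds
#'   within 40-300.
#' @param dbp_ratio_mean,dbp_ratio_sd DBP as a fraction of SBP (truncated to
#'   \[0.35, 0.85\]).
#' @param lactate_meanlog_intercept,lactate_meanlog_slope,lactate_sdlog
#'   Lognormal lactate: `meanlog = intercept + slope * (SI - 0.65)`.
#' @param ais_probs Probabilities of abdominal AIS 1..5.
#' @param fast_intercept,fast_slope FAST positivity: `logit p = intercept +
#'   slope * AIS`.
#' @param outcome_models Named list of `c(intercept, slope)` log-odds models
#'   on the FASILA total, for `transfusion`, `mtp`, `surgery`, `laparotomy`,
#'   `mortality`.
#' @param surgical_plus_ir_prob Fraction of surgical records also receiving
#'   interventional radiology.
#' @param ir_only_prob,conservative_plus_ir_prob Non-surgical management
#'   mixture.
#' @param iss_base,iss_slope,iss_sd ISS model (truncated normal, rounded,
#'   bounds 1-75): mean `iss_base + iss_slope * score`.
#' @param sofa_base,sofa_slope,sofa_sd SOFA model (bounds 0-24).
#' @param fibrinogen_base,fibrinogen_slope,fibrinogen_sd Fibrinogen model,
#'   g/L (bounds 0.5-8); the default slope is negative.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n = 400L,
                          penetrating_prob = 0.04,
                          male_prob = 0.90,
                          age_mean = 36.3, age_sd = 12.7,
                          age_bounds = c(18, 90),
                          hr_mean = 85, hr_sd = 20, hr_bounds = c(40, 180),
                          sbp_mean = 122, sbp_sd = 18,
                          sbp_bounds = c(70, 220),
                          dbp_ratio_mean = 0.60, dbp_ratio_sd = 0.06,
                          lactate_meanlog_intercept = log(1.6),
                          lactate_meanlog_slope = 0.9,
                          lactate_sdlog = 0.45,
                          ais_probs = c(0.15, 0.35, 0.30, 0.15, 0.05),
                          fast_intercept = -2.8, fast_slope = 0.75,
                          outcome_models = list(
                            transfusion = c(-2.6, 0.75),
                            mtp = c(-7.5, 1.2),
                            surgery = c(-2.2, 0.40),
                            laparotomy = c(-2.3, 0.40),
                            mortality = c(-4.3, 0.35)),
                          surgical_plus_ir_prob = 0.05,
                          ir_only_prob = 0.06,
                          conservative_plus_ir_prob = 0.015,
                          iss_base = 9, iss_slope = 2.5, iss_sd = 7,
                          sofa_base = 1, sofa_slope = 0.4, sofa_sd = 2,
                          fibrinogen_base = 2.9, fibrinogen_slope = -0.12,
                          fibrinogen_sd = 0.7) {
  config <- as.list(environment())
  problems <- character()
  for (p in c("penetrating_prob", "male_prob", "surgical_plus_ir_prob",
              "ir_only_prob", "conservative_plus_ir_prob")) {
    v <- config[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      problems <- c(problems, paste0(p, " must be a probability in [0,1]"))
  }
  if (config$n < 0) problems <- c(problems, "n must be non-negative")
  if (config$hr_bounds[1] < 20 || config$hr_bounds[2] > 250)
    problems <- c(problems, "hr_bounds must lie within 20-250")
  if (config$sbp_bounds[1] < 40 || config$sbp_bounds[2] > 300)
    problems <- c(problems, "sbp_bounds must lie within 40-300")
  if (abs(sum(config$ais_probs) - 1) > 1e-8 || any(config$ais_probs < 0))
    problems <- c(problems, "ais_probs must be non-negative and sum to 1")
  needed <- c("transfusion", "mtp", "surgery", "laparotomy", "mortality")
  if (!all(needed %in% names(config$outcome_models)))
    problems <- c(problems, paste("outcome_models must name:",
                                  paste(needed, collapse = ", ")))
  for (sdname in c("age_sd", "hr_sd", "sbp_sd", "dbp_ratio_sd",
                   "lactate_sdlog", "iss_sd", "sofa_sd", "fibrinogen_sd"))
    if (config[[sdname]] <= 0)
      problems <- c(problems, paste0(sdname, " must be positive"))
  if (length(problems))
    stop("invalid cohort config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(config, class = "cohort_config")
}

# inverse-CDF truncated normal draw (one uniform per observation)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate a synthetic trauma cohort
#'
#' Seeded and reproducible: the same seed and configuration always return
#' the identical cohort. Structural invariants are enforced after sampling
#' (massive transfusion implies transfusion and >= 10 blood units; the
#' `surgery` outcome is realized through the management category).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Cohort data frame in the [cohort_columns()] schema.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  if (!inherits(config, "cohort_config"))
    stop("config must be built with cohort_config()", call. = FALSE)
  n <- config$n
  if (n == 0) {
    empty <- expand_fixture(fixture_spec(rep(0L, 7),
      matrix(0L, 5, 7, dimnames = list(c("conservative", "surgical",
        "ir_only", "conservative_plus_ir", "surgical_plus_ir"), NULL)),
      rep(0L, 7), rep(0L, 7), rep(0L, 7), rep(0L, 7)))
    return(empty)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  mechanism <- ifelse(stats::runif(n) < config$penetrating_prob,
                      "penetrating", "blunt")
  sex <- ifelse(stats::runif(n) < config$male_prob, "male", "female")
  age <- round(.rtruncnorm(n, config$age_mean, config$age_sd,
                           config$age_bounds[1], config$age_bounds[2]), 1)
  hr <- round(.rtruncnorm(n, config$hr_mean, config$hr_sd,
                          config$hr_bounds[1], config$hr_bounds[2]))
  sbp <- round(.rtruncnorm(n, config$sbp_mean, config$sbp_sd,
                           config$sbp_bounds[1], config$sbp_bounds[2]))
  ratio <- .rtruncnorm(n, config$dbp_ratio_mean, config$dbp_ratio_sd,
                       0.35, 0.85)
  dbp <- round(sbp * ratio)
  si <- hr / sbp
  lactate <- round(stats::rlnorm(n,
    meanlog = config$lactate_meanlog_intercept +
      config$lactate_meanlog_slope * (si - 0.65),
    sdlog = config$lactate_sdlog), 1)
  abdominal_ais <- sample(seq_along(config$ais_probs), n, replace = TRUE,
                          prob = config$ais_probs)
  fast <- ifelse(stats::runif(n) < stats::plogis(
    config$fast_intercept + config$fast_slope * abdominal_ais),
    "positive", "negative")

  score <- fasila_score(fast, hr, sbp, lactate, indeterminate = "strict",
                        check_range = FALSE)$total

  draw_outcome <- function(model)
    stats::runif(n) < stats::plogis(model[1] + model[2] * score)
  transfused <- draw_outcome(config$outcome_models$transfusion)
  mtp <- draw_outcome(config$outcome_models$mtp)
  surgery <- draw_outcome(config$outcome_models$surgery)
  laparotomy <- draw_outcome(config$outcome_models$laparotomy)
  mortality <- draw_outcome(config$outcome_models$mortality)
  transfused <- transfused | mtp  # massive transfusion implies transfusion

  blood_units <- integer(n)
  blood_units[transfused] <- 2L + stats::rpois(sum(transfused), 2)
  blood_units[mtp] <- 10L + stats::rpois(sum(mtp), 4)

  u <- stats::runif(n)
  management <- ifelse(surgery,
    ifelse(u < config$surgical_plus_ir_prob, "surgical_plus_ir", "surgical"),
    ifelse(u < config$ir_only_prob, "ir_only",
      ifelse(u < config$ir_only_prob + config$conservative_plus_ir_prob,
             "conservative_plus_ir", "conservative")))

  iss <- pmin(75L, pmax(1L, round(.rtruncnorm(n,
    config$iss_base + config$iss_slope * score, config$iss_sd, 1, 75))))
  sofa <- pmin(24L, pmax(0L, round(.rtruncnorm(n,
    config$sofa_base + config$sofa_slope * score, config$sofa_sd, 0, 24))))
  fibrinogen <- round(.rtruncnorm(n,
    config$fibrinogen_base + config$fibrinogen_slope * score,
    config$fibrinogen_sd, 0.5, 8), 2)
  rts <- round(pmin(7.84, .rtruncnorm(n, 7.8 - 0.15 * score, 0.4, 0, 7.84)), 2)
  triss <- round(stats::plogis(3.8 - 0.35 * score +
                                 stats::rnorm(n, 0, 0.6)), 3)
  gcs <- 15L - stats::rbinom(n, 12L, stats::plogis(-3.2 + 0.3 * score))
  icu_los <- 1L + stats::rpois(n, 1.5 + 0.6 * score)
  hospital_los <- icu_los + stats::rpois(n, 4 + 1.5 * score)

  cohort <- data.frame(
    patient_id = sprintf("SIM-%05d", seq_len(n)),
    age = age, sex = sex, mechanism = mechanism,
    hr = hr, sbp = sbp, dbp = dbp, fast = fast, lactate = lactate,
    gcs = gcs, iss = iss, abdominal_ais = abdominal_ais,
    pelvic_ais = NA_integer_, rts = rts, triss = triss, sofa = sofa,
    fibrinogen = fibrinogen, transfused = transfused,
    blood_units = blood_units, mtp = mtp, laparotomy = laparotomy,
    management = management, icu_los = icu_los,
    hospital_los = hospital_los, mortality = mortality,
    stringsAsFactors = FALSE)
  validate_cohort(cohort)
}

#' Serialize a cohort configuration as JSON
#'
#' @param config A `cohort_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  obj <- unclass(config)
  obj$schema_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort configuration from JSON
#'
#' @param path Path to a JSON file written by [write_cohort_config()] (or
#'   hand-authored with the same fields; missing fields take defaults).
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$schema_version <- NULL
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown cohort config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(obj$outcome_models))
    obj$outcome_models <- lapply(obj$outcome_models, as.numeric)
  do.call(cohort_config, obj)
}
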
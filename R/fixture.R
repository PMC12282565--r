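# Deterministic reconstruction of the published 400-patient validation
# cohort from its printed per-score counts. Only the per-score marginals of
# each outcome are constrained; joint cross-tabulations between outcomes are
# reconstructions, not data, and are NOT claimed to match the source cohort.

#' Fixture specification constructor
#'
#' Exact per-score group sizes and per-score counts for each binary outcome,
#' used by [expand_fixture()] to emit patient-level records deterministically.
#'
#' @param group_sizes Integer vector of 7 group sizes (scores 0..6).
#' @param management 5 x 7 integer matrix of management counts, rows named
#'   `conservative`, `surgical`, `ir_only`, `conservative_plus_ir`,
#'   `surgical_plus_ir`; columns scores 0..6. Columns must sum to
#'   `group_sizes`.
#' @param laparotomy,transfusion,mtp,mortality Integer vectors of 7
#'   per-score outcome counts, each bounded by `group_sizes`; `mtp` must also
#'   be bounded by `transfusion` (massive transfusion implies transfusion).
#' @param males Per-score male counts (bounded by `group_sizes`).
#' @param label Free-text label recorded in serialized output.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(group_sizes, management, laparotomy, transfusion,
                         mtp, mortality, males = group_sizes,
                         label = "custom") {
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != 7 || any(group_sizes < 0))
    stop("group_sizes must be 7 non-negative integers", call. = FALSE)
  management <- as.matrix(management)
  storage.mode(management) <- "integer"
  mgmt_levels <- c("conservative", "surgical", "ir_only",
                   "conservative_plus_ir", "surgical_plus_ir")
  if (!all(dim(management) == c(5, 7)) ||
      !identical(rownames(management), mgmt_levels))
    stop("management must be a 5x7 matrix with rows ",
         paste(mgmt_levels, collapse = ", "), call. = FALSE)
  if (!all(colSums(management) == group_sizes))
    stop("management columns must sum to group_sizes", call. = FALSE)
  for (nm in c("laparotomy", "transfusion", "mtp", "mortality", "males")) {
    v <- get(nm)
    if (length(v) != 7 || any(v < 0) || any(v > group_sizes))
      stop(nm, " counts must be 7 integers bounded by group_sizes",
           call. = FALSE)
  }
  if (any(mtp > transfusion))
    stop("mtp counts cannot exceed transfusion counts", call. = FALSE)
  structure(list(group_sizes = group_sizes,
                 management = management,
                 laparotomy = as.integer(laparotomy),
                 transfusion = as.integer(transfusion),
                 mtp = as.integer(mtp),
                 mortality = as.integer(mortality),
                 males = as.integer(males),
                 label = label, schema_version = 1L),
            class = "fixture_spec")
}

#' The built-in 400-patient validation-cohort fixture
#'
#' Per-score group sizes 82/125/72/44/41/25/11 (n = 400) and the published
#' per-score counts for management (five categories), exploratory
#' laparotomy, blood transfusion (119 patients), massive transfusion
#' protocol activation (13) and in-hospital mortality (10). "Surgical
#' intervention" for diagnostic-panel purposes means management surgical or
#' surgical-plus-IR (97 patients in total; 33 in the high-score group).
#'
#' @return A `fixture_spec`.
#' @export
table1_fixture <- function() {
  mgmt <- rbind(
    conservative          = c(68, 98, 48, 25, 22,  9, 1),
    surgical              = c( 9, 19, 21, 15, 13, 10, 7),
    ir_only               = c( 3,  6,  3,  4,  4,  5, 1),
    conservative_plus_ir  = c( 2,  2,  0,  0,  2,  0, 0),
    surgical_plus_ir      = c( 0,  0,  0,  0,  0,  1, 2))
  fixture_spec(
    group_sizes = c(82, 125, 72, 44, 41, 25, 11),
    management = mgmt,
    laparotomy  = c(10, 15, 14, 13,  7, 10, 9),
    transfusion = c( 7, 26, 15, 19, 20, 21, 11),
    mtp         = c( 0,  0,  0,  0,  2,  4, 7),
    mortality   = c( 2,  2,  0,  1,  1,  2, 2),
    males       = c(74, 110, 68, 39, 38, 23, 9),
    label = "validation_cohort_n400")
}

# Canonical decomposition of a target total: fill SI points first, then
# lactate, then FAST. Only the total is constrained by the fixture.
.canonical_components <- function(total) {
  si <- pmin(total, 3L)
  rem <- total - si
  lac <- pmin(rem, 2L)
  fast <- rem - lac
  data.frame(fast_points = fast, si_points = si, lactate_points = lac)
}

# Representative vitals per component bin; back-solved so rescoring lands in
# the intended bin. Jitter is deliberately absent in fixture mode.
.si_bin_hr <- c(60, 75, 85, 100)    # with SBP 100 -> SI 0.60/0.75/0.85/1.00
.lactate_rep <- c(1.5, 3.0, 4.5)    # mmol/L for 0/1/2 points

# Per-score summary fills (reconstructions of printed stratum statistics,
# not patient data): age mean, ISS median, SOFA median, abdominal AIS mean,
# RTS mean, TRISS mean, GCS median, ICU and hospital LOS medians.
.fixture_fill <- list(
  age  = c(38.0, 37.3, 34.7, 32.9, 36.3, 32.8, 44.7),
  iss  = c(9, 14, 14, 17, 19, 22, 34),
  sofa = c(1, 1, 1, 2, 2, 2, 3),
  abdominal_ais = c(2, 3, 3, 3, 3, 3, 4),
  rts  = c(7.73, 7.79, 7.72, 7.52, 7.55, 7.17, 6.10),
  triss = c(0.98, 0.98, 0.98, 0.94, 0.95, 1.00, 0.70),
  gcs  = c(15, 15, 15, 15, 15, 15, 13),
  icu_los = c(2, 2, 2, 4, 4, 4, 6),
  hospital_los = c(5, 6, 6, 10, 18, 16, 18),
  # hypofibrinogenemia (< 2 g/L) counts apportioned to score levels by group
  # size (37 low-score, 18 high-score patients overall)
  hypofib = c(10, 14, 8, 5, 10, 6, 2),
  # penetrating mechanism: 14 low-score, 2 high-score patients overall
  penetrating = c(14, 0, 0, 0, 2, 0, 0))

#' Expand a fixture specification into patient-level records
#'
#' Emits one record per patient, deterministically: each record's FASILA
#' components are the canonical decomposition of its score level (SI points
#' filled first, then lactate, then FAST) with vitals and lactate back-solved
#' to land in the required bins; within each score level, management
#' categories are laid out surgical-first and every other outcome flag is
#' assigned to the first k records, so all per-score, per-outcome counts
#' match the specification exactly while joint cross-tabulations are
#' reconstructions. Running [score_cohort()] on the result reproduces every
#' intended score level (round-trip identity). Repeated calls are
#' byte-identical.
#'
#' @param spec A `fixture_spec`, e.g. [table1_fixture()].
#' @return A cohort data frame in the [cohort_columns()] schema.
#' @export
expand_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mgmt_levels <- rownames(spec$management)
  # surgical-first ordering keeps laparotomy/transfusion flags overlapping
  # the operative records
  mgmt_order <- c("surgical", "surgical_plus_ir", "ir_only",
                  "conservative_plus_ir", "conservative")
  rows <- vector("list", 7L)
  for (s in 0:6) {
    k <- spec$group_sizes[s + 1]
    if (k == 0) { rows[[s + 1]] <- NULL; next }
    comp <- .canonical_components(s)
    idx <- seq_len(k)
    management <- rep(mgmt_order,
                      times = spec$management[mgmt_order, s + 1])
    first_k <- function(count) idx <= count
    hr <- .si_bin_hr[comp$si_points + 1]
    mtp_flag <- first_k(spec$mtp[s + 1])
    tx_flag <- first_k(spec$transfusion[s + 1])
    rows[[s + 1]] <- data.frame(
      patient_id = sprintf("F%d-%03d", s, idx),
      age = .fixture_fill$age[s + 1],
      sex = ifelse(first_k(spec$males[s + 1]), "male", "female"),
      mechanism = ifelse(first_k(.fixture_fill$penetrating[s + 1]),
                         "penetrating", "blunt"),
      hr = hr,
      sbp = 100,
      dbp = 60,
      fast = ifelse(comp$fast_points == 1, "positive", "negative"),
      lactate = .lactate_rep[comp$lactate_points + 1],
      gcs = .fixture_fill$gcs[s + 1],
      iss = .fixture_fill$iss[s + 1],
      abdominal_ais = .fixture_fill$abdominal_ais[s + 1],
      pelvic_ais = NA_integer_,
      rts = .fixture_fill$rts[s + 1],
      triss = .fixture_fill$triss[s + 1],
      sofa = .fixture_fill$sofa[s + 1],
      fibrinogen = ifelse(first_k(.fixture_fill$hypofib[s + 1]), 1.6, 2.6),
      transfused = tx_flag,
      blood_units = ifelse(mtp_flag, 12L, ifelse(tx_flag, 3L, 0L)),
      mtp = mtp_flag,
      laparotomy = first_k(spec$laparotomy[s + 1]),
      management = management,
      icu_los = .fixture_fill$icu_los[s + 1],
      hospital_los = .fixture_fill$hospital_los[s + 1],
      mortality = first_k(spec$mortality[s + 1]),
      stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  if (is.null(cohort))
    cohort <- as.data.frame(stats::setNames(
      replicate(length(.cohort_columns), logical(0), simplify = FALSE),
      .cohort_columns))
  rownames(cohort) <- NULL
  validate_cohort(cohort)
}

#' Serialize / deserialize a fixture specification as JSON
#'
#' @param spec A `fixture_spec`.
#' @param path Output (or input) path.
#' @return `path` for write; a `fixture_spec` for read.
#' @export
write_fixture_spec <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  obj <- unclass(spec)
  obj$management <- lapply(stats::setNames(rownames(spec$management),
                                           rownames(spec$management)),
                           function(r) unname(spec$management[r, ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fixture_spec
#' @export
read_fixture_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mgmt_levels <- c("conservative", "surgical", "ir_only",
                   "conservative_plus_ir", "surgical_plus_ir")
  mgmt <- do.call(rbind, obj$management[mgmt_levels])
  fixture_spec(obj$group_sizes, mgmt, obj$laparotomy, obj$transfusion,
               obj$mtp, obj$mortality, obj$males, obj$label)
}
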
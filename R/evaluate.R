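# Full evaluation of a scored cohort: low/high group comparison, correlation
# panel against the FASILA total, diagnostic panels at the published binary
# thresholds, AUROC comparison across scoring tools, logistic regression for
# transfusion, and post-hoc power. Every reported number is produced by the
# underlying exported operations; the report layer does no arithmetic of its
# own.

#' Evaluate a scored cohort
#'
#' @param scored A cohort scored by [score_cohort()] (the appended score
#'   columns must be present).
#' @param cutoff Low/high FASILA cutoff, default 4.
#' @param ci_method Binomial CI method for diagnostic metrics.
#' @param n_boot Bootstrap replicates for the AUROC comparison.
#' @param seed Seed for the bootstrap.
#' @param panel_outcome Outcome preset for the diagnostic panels (default
#'   `"surgery"`: management surgical or surgical-plus-IR).
#' @param roc_outcomes Outcome presets for the AUROC comparison set.
#' @return An `evaluation_report` list with elements `meta`,
#'   `group_comparison`, `correlations`, `diagnostic_panel`, `auroc`,
#'   `logistic_transfusion`, `power`.
#' @export
evaluate_cohort <- function(scored, cutoff = 4L,
                            ci_method = c("clopper_pearson", "wilson"),
                            n_boot = 2000L, seed = 1L,
                            panel_outcome = "surgery",
                            roc_outcomes = c("mtp", "transfusion", "surgery")) {
  ci_method <- match.arg(ci_method)
  needed <- c("fasila_total", "systolic_si", "diastolic_si", "abc_total")
  if (!all(needed %in% names(scored)))
    stop("cohort is not scored; run score_cohort() first", call. = FALSE)
  usable <- !is.na(scored$fasila_total)
  n_flagged <- sum(!usable)
  data <- scored[usable, , drop = FALSE]

  oc_check <- outcome_vector(data, panel_outcome)
  if (!any(oc_check) || all(oc_check))
    stop("outcome '", panel_outcome, "' has a single class in this cohort",
         call. = FALSE)

  high <- data$fasila_total >= cutoff
  meta <- list(n = nrow(scored), n_scored = nrow(data),
               n_flagged = n_flagged, cutoff = cutoff,
               ci_method = ci_method, n_boot = n_boot, seed = seed,
               package_version = as.character(utils::packageVersion("fasila")))

  group_cmp <- .group_comparison_table(data, high)
  correlations <- .correlation_table(data)
  panel <- .diagnostic_panel_table(data, cutoff, ci_method, panel_outcome)
  auroc <- .auroc_table(data, roc_outcomes, n_boot, seed)
  logistic <- .transfusion_regression(data)
  power <- .transfusion_power(data, high)

  structure(list(meta = meta, group_comparison = group_cmp,
                 correlations = correlations, diagnostic_panel = panel,
                 auroc = auroc, logistic_transfusion = logistic,
                 power = power),
            class = "evaluation_report")
}

.group_comparison_table <- function(data, high) {
  n_low <- sum(!high); n_high <- sum(high)
  cat_row <- function(flag) {
    tab <- rbind(low = c(sum(flag & !high), sum(!flag & !high)),
                 high = c(sum(flag & high), sum(!flag & high)))
    p <- tryCatch(group_comparison(tab, "chi_square")$p_two_sided,
                  error = function(e) NA_real_)
    list(low_count = sum(flag & !high), low_pct = 100 * mean(flag[!high]),
         high_count = sum(flag & high), high_pct = 100 * mean(flag[high]),
         p = p)
  }
  num_row <- function(x) {
    lo <- x[!high & !is.na(x)]; hi <- x[high & !is.na(x)]
    p <- if (length(lo) >= 2 && length(hi) >= 2)
      group_comparison(list(lo, hi), "welch_t")$p_two_sided else NA_real_
    list(low_mean = mean(lo), low_sd = stats::sd(lo),
         high_mean = mean(hi), high_sd = stats::sd(hi), p = p)
  }
  list(
    n_low = n_low, n_high = n_high,
    categorical = list(
      male = cat_row(data$sex == "male"),
      penetrating = cat_row(data$mechanism == "penetrating"),
      laparotomy = cat_row(outcome_vector(data, "laparotomy")),
      surgery = cat_row(outcome_vector(data, "surgery")),
      transfusion = cat_row(outcome_vector(data, "transfusion")),
      mtp = cat_row(outcome_vector(data, "mtp")),
      mortality = cat_row(outcome_vector(data, "mortality")),
      hypofibrinogenemia = cat_row(!is.na(data$fibrinogen) &
                                     data$fibrinogen < 2.0)),
    continuous = list(
      age = num_row(data$age),
      systolic_si = num_row(data$systolic_si),
      diastolic_si = num_row(data$diastolic_si),
      iss = num_row(data$iss),
      abdominal_ais = num_row(data$abdominal_ais),
      sofa = num_row(data$sofa)))
}

.correlation_table <- function(data) {
  partners <- list(
    systolic_si = data$systolic_si,
    rts = data$rts,
    triss = data$triss,
    iss = data$iss,
    lactate = data$lactate,
    sofa = data$sofa,
    blood_units = ifelse(outcome_vector(data, "transfusion"),
                         data$blood_units, NA_real_),
    icu_los = data$icu_los,
    fibrinogen = data$fibrinogen,
    abdominal_ais = data$abdominal_ais)
  lapply(partners, function(y) {
    res <- tryCatch(pearson_correlation(data$fasila_total, y),
                    error = function(e) NULL)
    if (is.null(res)) list(r = NA_real_, n = sum(stats::complete.cases(
      data$fasila_total, y)), p = NA_real_)
    else list(r = res$r, n = res$n, p = res$p_two_sided)
  })
}

.diagnostic_panel_table <- function(data, cutoff, ci_method, panel_outcome) {
  outcome <- outcome_vector(data, panel_outcome)
  tests <- list(
    fasila = list(scores = data$fasila_total, cutoff = cutoff,
                  label = sprintf("FASILA >= %d", cutoff)),
    systolic_si = list(scores = data$systolic_si, cutoff = 0.80 + 1e-9,
                       label = "Systolic SI > 0.80"),
    diastolic_si = list(scores = data$diastolic_si, cutoff = 2.2 + 1e-9,
                        label = "Diastolic SI > 2.2"))
  out <- lapply(tests, function(t) {
    conf <- confusion_from_threshold(t$scores, outcome, t$cutoff)
    panel <- diagnostic_metrics(conf, ci_method = ci_method)
    roc <- auroc_mann_whitney(t$scores, outcome)
    or <- tryCatch(odds_ratio(conf), error = function(e) NULL)
    list(label = t$label,
         confusion = unclass(conf)[c("tp", "fp", "fn", "tn")],
         sensitivity = .ci_list(panel$sensitivity),
         specificity = .ci_list(panel$specificity),
         ppv = .ci_list(panel$ppv),
         npv = .ci_list(panel$npv),
         auc_binary = panel$auc_binary,
         auc_continuous = roc$auc,
         odds_ratio = if (is.null(or)) NULL else
           list(or = or$or_estimate, lo = or$lo, hi = or$hi,
                continuity_corrected = or$continuity_corrected))
  })
  c(list(outcome = panel_outcome), out)
}

.ci_list <- function(ci)
  list(estimate = ci$estimate, lo = ci$lo, hi = ci$hi)

.auroc_table <- function(data, roc_outcomes, n_boot, seed) {
  scores <- list(fasila = data$fasila_total, abc = data$abc_total,
                 systolic_si = data$systolic_si,
                 diastolic_si = data$diastolic_si, sofa = data$sofa)
  out <- lapply(stats::setNames(roc_outcomes, roc_outcomes), function(oc) {
    outcome <- outcome_vector(data, oc)
    if (!any(outcome) || all(outcome))
      return(list(error = "single-class outcome"))
    aucs <- lapply(scores, function(s) {
      tryCatch(auroc_mann_whitney(s, outcome)$auc,
               error = function(e) NA_real_)
    })
    cmp <- auroc_bootstrap_compare(data$fasila_total, data$abc_total,
                                   outcome, n_boot = n_boot, seed = seed)
    list(auc = aucs,
         fasila_vs_abc = list(delta = cmp$delta,
                              ci = unname(cmp$ci_delta),
                              n_boot = cmp$n_boot))
  })
  out
}

.transfusion_regression <- function(data) {
  predictors <- c("fasila_total", "abdominal_ais", "iss", "sofa", "fibrinogen")
  outcome <- outcome_vector(data, "transfusion")
  keep <- stats::complete.cases(data[predictors])
  n_dropped <- sum(!keep)
  X <- as.matrix(data[keep, predictors])
  y <- outcome[keep]
  fit <- tryCatch(logistic_irls(X, y), error = function(e) e)
  if (inherits(fit, "error"))
    return(list(error = conditionMessage(fit), n_dropped = n_dropped))
  list(terms = logistic_summary(fit), converged = fit$converged,
       iterations = fit$iterations, n = fit$n, n_dropped = n_dropped)
}

.transfusion_power <- function(data, high) {
  tx <- outcome_vector(data, "transfusion")
  n1 <- sum(!high); n2 <- sum(high)
  if (n1 < 2 || n2 < 2) return(list(error = "group too small"))
  p1 <- mean(tx[!high]); p2 <- mean(tx[high])
  list(p_low = p1, p_high = p2, n_low = n1, n_high = n2,
       power = two_proportion_power(p1, p2, n1, n2))
}

#' Write an evaluation report as JSON and text tables
#'
#' The JSON is deterministic (fixed digit budget, stable key order from the
#' report structure); the text rendering mirrors the published table layout:
#' low-vs-high comparison, correlation panel, diagnostic panel with 1-decimal
#' percentages, and the AUROC set at 2 decimals.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @param basename File stem, default `"report"`.
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_report <- function(report, dir, basename = "report") {
  stopifnot(inherits(report, "evaluation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, paste0(basename, ".json"))
  txt_path <- file.path(dir, paste0(basename, ".txt"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = 10, na = "null", pretty = TRUE)
  writeLines(format_report(report), txt_path)
  invisible(c(json = json_path, text = txt_path))
}

#' Render an evaluation report as text tables
#'
#' @param report An `evaluation_report`.
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  pct <- function(x) sprintf("%.1f%%", 100 * x)
  lines <- c(
    sprintf("Cohort: n = %d (%d scored, %d flagged); cutoff %d",
            report$meta$n, report$meta$n_scored, report$meta$n_flagged,
            report$meta$cutoff),
    "",
    sprintf("== Low (< %d, n = %d) vs high (>= %d, n = %d) ==",
            report$meta$cutoff, report$group_comparison$n_low,
            report$meta$cutoff, report$group_comparison$n_high))
  for (nm in names(report$group_comparison$categorical)) {
    r <- report$group_comparison$categorical[[nm]]
    lines <- c(lines, sprintf("%-20s %4d (%s) vs %4d (%s)  p = %s", nm,
                              r$low_count, pct(r$low_pct / 100),
                              r$high_count, pct(r$high_pct / 100),
                              .fmt_p(r$p)))
  }
  for (nm in names(report$group_comparison$continuous)) {
    r <- report$group_comparison$continuous[[nm]]
    lines <- c(lines, sprintf("%-20s %.2f +/- %.2f vs %.2f +/- %.2f  p = %s",
                              nm, r$low_mean, r$low_sd, r$high_mean,
                              r$high_sd, .fmt_p(r$p)))
  }
  lines <- c(lines, "", "== Pearson correlation with FASILA total ==")
  for (nm in names(report$correlations)) {
    r <- report$correlations[[nm]]
    lines <- c(lines, sprintf("%-20s r = %6s  n = %4d  p = %s", nm,
                              ifelse(is.na(r$r), "NA", sprintf("%.3f", r$r)),
                              r$n, .fmt_p(r$p)))
  }
  lines <- c(lines, "",
             sprintf("== Diagnostic panel (outcome: %s) ==",
                     report$diagnostic_panel$outcome))
  for (nm in setdiff(names(report$diagnostic_panel), "outcome")) {
    t <- report$diagnostic_panel[[nm]]
    ci <- function(m) sprintf("%s (%s-%s)", pct(m$estimate), pct(m$lo),
                              pct(m$hi))
    lines <- c(lines,
      sprintf("%s  [tp %d fp %d fn %d tn %d]", t$label, t$confusion$tp,
              t$confusion$fp, t$confusion$fn, t$confusion$tn),
      sprintf("  sens %s  spec %s", ci(t$sensitivity), ci(t$specificity)),
      sprintf("  ppv  %s  npv  %s", ci(t$ppv), ci(t$npv)),
      sprintf("  AUC: binary (sens+spec)/2 = %.2f; continuous score = %.2f",
              t$auc_binary, t$auc_continuous))
  }
  lines <- c(lines, "", "== AUROC by outcome (tie-aware Mann-Whitney) ==")
  for (oc in names(report$auroc)) {
    r <- report$auroc[[oc]]
    if (!is.null(r$error)) {
      lines <- c(lines, sprintf("%s: %s", oc, r$error)); next
    }
    aucs <- vapply(r$auc, function(a)
      ifelse(is.na(a), "NA", sprintf("%.2f", a)), character(1))
    lines <- c(lines,
      sprintf("%-12s %s", oc,
              paste(sprintf("%s %s", names(aucs), aucs), collapse = "  ")),
      sprintf("  FASILA - ABC delta = %.3f (95%% CI %.3f to %.3f, %d reps)",
              r$fasila_vs_abc$delta, r$fasila_vs_abc$ci[1],
              r$fasila_vs_abc$ci[2], r$fasila_vs_abc$n_boot))
  }
  lines <- c(lines, "", "== Logistic regression: blood transfusion ==")
  lg <- report$logistic_transfusion
  if (!is.null(lg$error)) {
    lines <- c(lines, paste("regression failed:", lg$error))
  } else {
    for (i in seq_len(nrow(lg$terms))) {
      tr <- lg$terms[i, ]
      lines <- c(lines, sprintf("%-14s OR %.2f (%.2f-%.2f)  p = %s",
                                tr$term, tr$or, tr$or_lo, tr$or_hi,
                                .fmt_p(tr$p)))
    }
    lines <- c(lines, sprintf("n = %d (%d rows dropped, listwise); %s in %d iterations",
                              lg$n, lg$n_dropped,
                              ifelse(lg$converged, "converged", "NOT converged"),
                              lg$iterations))
  }
  pw <- report$power
  if (is.null(pw$error))
    lines <- c(lines, "",
      sprintf("Post-hoc two-proportion power (transfusion %.1f%% vs %.1f%%): %.4f",
              100 * pw$p_low, 100 * pw$p_high, pw$power))
  lines
}

.fmt_p <- function(p) {
  if (is.null(p) || is.na(p)) return("NA")
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
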
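#' Build a 2x2 confusion table from a score threshold
#'
#' Test-positive means `score >= cutoff`; condition-positive means
#' `outcome == TRUE`.
#'
#' @param scores Ordinal score per patient (no missing values).
#' @param outcome Logical outcome per patient, same length.
#' @param cutoff Score threshold.
#' @return A `binary_confusion` list with fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_from_threshold <- function(scores, outcome, cutoff) {
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  if (length(scores) != length(outcome))
    stop("scores and outcome lengths differ", call. = FALSE)
  if (anyNA(scores) || anyNA(outcome))
    stop("missing values in scores or outcome", call. = FALSE)
  outcome <- as.logical(outcome)
  pos <- scores >= cutoff
  binary_confusion(tp = sum(pos & outcome), fp = sum(pos & !outcome),
                   fn = sum(!pos & outcome), tn = sum(!pos & !outcome))
}

#' Construct a binary confusion table
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return A `binary_confusion` object.
#' @export
binary_confusion <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0))
    stop("confusion cells must be non-negative counts", call. = FALSE)
  cells <- stats::setNames(as.list(as.integer(round(cells))), names(cells))
  structure(cells, class = "binary_confusion")
}

#' @export
print.binary_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test+", "test-"), c("outcome+", "outcome-")))
  print(m)
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' Clopper-Pearson exact (default) via the beta quantile identity, or Wilson
#' score interval.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param method `"clopper_pearson"` or `"wilson"`.
#' @param level Confidence level, default 0.95.
#' @return A `proportion_ci` list: `estimate`, `lo`, `hi`, `method`, `level`,
#'   `x`, `n`. For `n = 0` the estimate and bounds are `NA` (undefined).
#' @export
proportion_ci <- function(x, n, method = c("clopper_pearson", "wilson"),
                          level = 0.95) {
  method <- match.arg(method)
  if (n == 0) {
    out <- list(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                method = method, level = level, x = x, n = n)
    class(out) <- "proportion_ci"
    return(out)
  }
  alpha <- 1 - level
  p <- x / n
  if (method == "clopper_pearson") {
    lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- if (x == 0) 0 else max(0, centre - half)
    hi <- if (x == n) 1 else min(1, centre + half)
  }
  structure(list(estimate = p, lo = lo, hi = hi, method = method,
                 level = level, x = x, n = n),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.3f (%s %.0f%% CI %.3f-%.3f; %d/%d)\n", x$estimate,
              x$method, 100 * x$level, x$lo, x$hi, x$x, x$n))
  invisible(x)
}

#' Diagnostic-accuracy panel for a binary test
#'
#' Sensitivity, specificity, PPV and NPV with binomial confidence intervals,
#' plus the AUROC implied by the binary (thresholded) test,
#' `(sensitivity + specificity) / 2`. A metric whose denominator is zero is
#' reported as undefined (`NA`), never silently 0.
#'
#' @param confusion A `binary_confusion`, e.g. from
#'   [confusion_from_threshold()].
#' @param ci_method,level Passed to [proportion_ci()].
#' @return A `diagnostic_panel` list of four `proportion_ci` objects plus
#'   `auc_binary`.
#' @export
diagnostic_metrics <- function(confusion,
                               ci_method = c("clopper_pearson", "wilson"),
                               level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(confusion, "binary_confusion"))
  with(confusion, {
    if (tp + fn == 0 || fp + tn == 0)
      stop("need at least one condition-positive and one condition-negative",
           call. = FALSE)
    panel <- list(
      sensitivity = proportion_ci(tp, tp + fn, ci_method, level),
      specificity = proportion_ci(tn, tn + fp, ci_method, level),
      ppv = proportion_ci(tp, tp + fp, ci_method, level),
      npv = proportion_ci(tn, tn + fn, ci_method, level))
    panel$auc_binary <-
      (panel$sensitivity$estimate + panel$specificity$estimate) / 2
    panel$confusion <- confusion
    class(panel) <- "diagnostic_panel"
    panel
  })
}

#' @export
print.diagnostic_panel <- function(x, digits = 1, ...) {
  pct <- function(ci) {
    if (is.na(ci$estimate)) return("undefined")
    sprintf(paste0("%.", digits, "f%% (%.", digits, "f%%-%.", digits, "f%%)"),
            100 * ci$estimate, 100 * ci$lo, 100 * ci$hi)
  }
  cat("Sensitivity:", pct(x$sensitivity), "\n")
  cat("Specificity:", pct(x$specificity), "\n")
  cat("PPV:        ", pct(x$ppv), "\n")
  cat("NPV:        ", pct(x$npv), "\n")
  cat(sprintf("Binary-test AUROC (sens+spec)/2: %.2f\n", x$auc_binary))
  invisible(x)
}

#' Odds ratio with Woolf (log-scale) confidence interval
#'
#' `OR = (tp * tn) / (fp * fn)`. If any cell is zero the Haldane-Anscombe
#' +0.5 continuity correction is applied to every cell and the result is
#' flagged. Two zero cells in the same row or column leave the odds ratio
#' undefined and raise an error.
#'
#' @param confusion A `binary_confusion`.
#' @param level Confidence level, default 0.95.
#' @return An `odds_ratio_result` list: `or_estimate`, `lo`, `hi`,
#'   `continuity_corrected`, `level`.
#' @export
odds_ratio <- function(confusion, level = 0.95) {
  stopifnot(inherits(confusion, "binary_confusion"))
  a <- confusion$tp; b <- confusion$fp; c <- confusion$fn; d <- confusion$tn
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop("odds ratio undefined: a full row or column of the 2x2 is zero",
         call. = FALSE)
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(or_estimate = or,
                 lo = exp(log(or) - z * se),
                 hi = exp(log(or) + z * se),
                 continuity_corrected = corrected,
                 level = level),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.3f (%.0f%% CI %.3f-%.3f)%s\n", x$or_estimate,
              100 * x$level, x$lo, x$hi,
              if (x$continuity_corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}
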
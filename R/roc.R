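#' Tie-aware ROC curve and Mann-Whitney AUROC
#'
#' The area under the ROC curve is computed as the Mann-Whitney probability
#' estimator: over all positive-negative patient pairs, the proportion of
#' pairs where the positive scores higher, counting ties as 1/2. This equals
#' trapezoidal integration of the empirical ROC curve through tied groups.
#' Operating points are taken at every distinct score value, thresholds
#' descending, so the curve runs from (0, 0) to (1, 1).
#'
#' @param scores Ordinal score per patient (higher = more at risk).
#' @param outcome Logical outcome per patient.
#' @return A `roc_curve` list: `thresholds` (descending; the leading `Inf`
#'   gives the (0,0) endpoint), `fpr`, `tpr`, `auc`, `n_pos`, `n_neg`.
#' @export
auroc_mann_whitney <- function(scores, outcome) {
  if (length(scores) != length(outcome))
    stop("scores and outcome lengths differ", call. = FALSE)
  keep <- !(is.na(scores) | is.na(outcome))
  scores <- scores[keep]; outcome <- as.logical(outcome[keep])
  n_pos <- sum(outcome); n_neg <- sum(!outcome)
  if (n_pos == 0 || n_neg == 0)
    stop("outcome has a single class; AUROC undefined", call. = FALSE)

  # midranks handle ties exactly: AUC = (R_pos - n_pos(n_pos+1)/2)/(n_pos*n_neg)
  r <- rank(scores)
  auc <- (sum(r[outcome]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(outcome & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!outcome & scores >= t), numeric(1))
  structure(list(thresholds = c(Inf, thr),
                 fpr = c(0, fp / n_neg),
                 tpr = c(0, tp / n_pos),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, %d operating points\n",
              x$n_pos, x$n_neg, length(x$thresholds)))
  cat(sprintf("AUROC (tie-aware Mann-Whitney): %.4f\n", x$auc))
  invisible(x)
}

#' Export ROC operating points as a data frame
#'
#' @param roc A `roc_curve`.
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr)
}

#' Compare two AUROCs on the same patients by stratified bootstrap
#'
#' Both scores are measured on the same patients, so their AUROCs are
#' correlated; the comparison resamples patients (cases and controls
#' separately, preserving prevalence) and recomputes both AUROCs in each
#' replicate. Percentile intervals are reported for each AUROC and for the
#' difference. Identical score vectors give a difference of exactly zero in
#' every replicate.
#'
#' @param scores_a,scores_b Score vectors aligned to the same patients.
#' @param outcome Logical outcome vector.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; resampling is reproducible given the seed.
#' @param level Confidence level, default 0.95.
#' @return An `auroc_comparison` list: `auc_a`, `auc_b`, `delta`
#'   (a - b), percentile CIs `ci_a`, `ci_b`, `ci_delta`, and `n_boot`.
#' @export
auroc_bootstrap_compare <- function(scores_a, scores_b, outcome,
                                    n_boot = 2000L, seed = 1L, level = 0.95) {
  if (length(scores_a) != length(outcome) ||
      length(scores_b) != length(outcome))
    stop("score vectors must align with outcome", call. = FALSE)
  keep <- !(is.na(scores_a) | is.na(scores_b) | is.na(outcome))
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]
  outcome <- as.logical(outcome[keep])
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  idx_pos <- which(outcome); idx_neg <- which(!outcome)
  if (!length(idx_pos) || !length(idx_neg))
    stop("outcome has a single class; AUROC undefined", call. = FALSE)

  auc_of <- function(s, o) {
    np <- sum(o); nn <- sum(!o)
    r <- rank(s)
    (sum(r[o]) - np * (np + 1) / 2) / (np * nn)
  }
  auc_a <- auc_of(scores_a, outcome)
  auc_b <- auc_of(scores_b, outcome)

  boot_a <- boot_b <- numeric(n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (i in seq_len(n_boot)) {
    take <- c(idx_pos[sample.int(length(idx_pos), replace = TRUE)],
              idx_neg[sample.int(length(idx_neg), replace = TRUE)])
    o <- outcome[take]
    boot_a[i] <- auc_of(scores_a[take], o)
    boot_b[i] <- auc_of(scores_b[take], o)
  }
  alpha <- 1 - level
  q <- function(x) unname(stats::quantile(x, c(alpha / 2, 1 - alpha / 2),
                                          type = 7))
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b,
                 ci_a = q(boot_a), ci_b = q(boot_b),
                 ci_delta = q(boot_a - boot_b),
                 boot_delta = boot_a - boot_b,
                 n_boot = n_boot, seed = seed, level = level),
            class = "auroc_comparison")
}

#' @export
print.auroc_comparison <- function(x, ...) {
  cat(sprintf("AUROC A: %.3f (%.3f-%.3f)\n", x$auc_a, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("AUROC B: %.3f (%.3f-%.3f)\n", x$auc_b, x$ci_b[1], x$ci_b[2]))
  cat(sprintf("Delta (A-B): %.3f (%.3f-%.3f), %d stratified bootstrap reps\n",
              x$delta, x$ci_delta[1], x$ci_delta[2], x$n_boot))
  invisible(x)
}

# Preserve the caller's RNG state around seeded internals.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
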
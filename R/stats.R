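#' Pearson correlation with pairwise deletion
#'
#' Product-moment correlation on complete pairs; the two-sided p-value uses
#' the exact t transform `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of
#' freedom. Incomplete pairs are dropped (pairwise deletion), matching how
#' correlation matrices with per-pair N are usually reported.
#'
#' @param x,y Paired numeric vectors.
#' @return A `correlation_result` list: `r`, `n` (pairs used), `p_two_sided`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, n = n, p_two_sided = p), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, two-sided p = %.4g)\n",
              x$r, x$n, x$p_two_sided))
  invisible(x)
}

#' Fisher's exact test p-value for a 2x2 table
#'
#' Conditional two-sided p by hypergeometric enumeration: with both margins
#' fixed, sum the probabilities of every table as or less probable than the
#' observed one (the standard "sum of small p" definition). A small relative
#' tolerance guards against floating-point ties.
#'
#' @param tab 2x2 matrix of counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_p <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0))
    stop("need a 2x2 table of non-negative counts", call. = FALSE)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' Group comparison tests
#'
#' Dispatches the comparison the data call for: Pearson chi-square or
#' Fisher's exact test on contingency counts, Welch's t on two numeric
#' samples, one-way ANOVA on k numeric samples. When a chi-square is
#' requested but any expected cell count falls below 5, the function falls
#' back to Fisher's exact test for 2x2 tables and flags the switch.
#'
#' @param data For `chi_square`/`fisher_exact`: a matrix of counts (rows =
#'   groups). For `welch_t`/`one_way_anova`: a list of numeric vectors, one
#'   per group, each with n >= 2.
#' @param test One of `"chi_square"`, `"fisher_exact"`, `"welch_t"`,
#'   `"one_way_anova"`.
#' @return A `group_comparison` list: `test` (the test actually used),
#'   `statistic` (NA for Fisher), `p_two_sided`, `fallback` (logical).
#' @export
group_comparison <- function(data, test = c("chi_square", "fisher_exact",
                                            "welch_t", "one_way_anova")) {
  test <- match.arg(test)
  fallback <- FALSE
  if (test %in% c("chi_square", "fisher_exact")) {
    tab <- as.matrix(data)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("degenerate table: empty row or column", call. = FALSE)
    if (test == "chi_square") {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5) && all(dim(tab) == 2)) {
        test <- "fisher_exact"; fallback <- TRUE
      }
    }
    if (test == "chi_square") {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      res <- list(statistic = unname(ct$statistic), p = ct$p.value)
    } else {
      if (!all(dim(tab) == 2))
        stop("fisher_exact implemented for 2x2 tables", call. = FALSE)
      res <- list(statistic = NA_real_, p = fisher_exact_p(tab))
    }
  } else {
    groups <- data
    if (!is.list(groups) || length(groups) < 2)
      stop("need a list of >= 2 numeric groups", call. = FALSE)
    if (any(vapply(groups, length, integer(1)) < 2))
      stop("each group needs n >= 2", call. = FALSE)
    if (test == "welch_t") {
      if (length(groups) != 2) stop("welch_t needs exactly 2 groups", call. = FALSE)
      tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE)
      res <- list(statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      values <- unlist(groups, use.names = FALSE)
      g <- factor(rep(seq_along(groups),
                      vapply(groups, length, integer(1))))
      av <- stats::oneway.test(values ~ g, var.equal = TRUE)
      res <- list(statistic = unname(av$statistic), p = av$p.value)
    }
  }
  structure(list(test = test, statistic = res$statistic,
                 p_two_sided = res$p, fallback = fallback),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %s, two-sided p = %.4g\n", x$test,
              if (x$fallback) " (fallback from chi_square)" else "",
              if (is.na(x$statistic)) "-" else sprintf("%.4f", x$statistic),
              x$p_two_sided))
  invisible(x)
}

#' Power of the two-proportion z test
#'
#' Normal-approximation power for a two-sided test of p1 = p2: the null
#' standard error pools the proportions, the alternative standard error does
#' not. Used post hoc to assess achieved power at observed group proportions
#' and sizes.
#'
#' @param p1,p2 Group proportions in (0, 1) (one may be 0 or 1; the unpooled
#'   alternative SE then has a zero contribution from that group).
#' @param n1,n2 Group sizes, each >= 2.
#' @param alpha Two-sided significance level, default 0.05.
#' @return Power in `[0, 1]`.
#' @export
two_proportion_power <- function(p1, p2, n1, n2, alpha = 0.05) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  d <- abs(p1 - p2)
  z <- stats::qnorm(1 - alpha / 2)
  if (se1 == 0) return(as.numeric(d > z * se0))
  stats::pnorm((d - z * se0) / se1) + stats::pnorm((-d - z * se0) / se1)
}
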
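#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit written against the IRLS normal
#' equations, with Wald standard errors from the inverse Fisher information
#' at convergence and odds ratios `exp(beta)` with 95% Wald intervals.
#' Convergence is declared when the largest coefficient change falls below
#' `tol`. Perfect separation (coefficients diverging while fitted
#' probabilities saturate) and rank-deficient designs raise explicit errors
#' rather than returning a silently unstable fit.
#'
#' @param design Numeric matrix of predictors (no intercept column; one is
#'   added). Column names become coefficient names.
#' @param outcome Logical (or 0/1) response vector.
#' @param max_iter Maximum IRLS iterations, default 100.
#' @param tol Convergence tolerance on the max absolute coefficient change,
#'   default 1e-8.
#' @return A `logistic_fit` list: `coefficients` (log-odds scale, including
#'   `(Intercept)`), `se`, `or`, `or_lo`, `or_hi`, `z`, `p`, `converged`,
#'   `iterations`, `loglik` (per-iteration trace), `n`.
#' @export
logistic_irls <- function(design, outcome, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(design)
  y <- as.numeric(outcome)
  if (anyNA(X) || anyNA(y))
    stop("missing values in design or outcome; apply listwise deletion first",
         call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  if (nrow(X) != length(y)) stop("design rows must match outcome", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)
  if (qr(X)$rank < p)
    stop("rank-deficient design (collinear predictors)", call. = FALSE)

  beta <- numeric(p)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    loglik <- c(loglik, sum(y * eta - log1p(exp(eta))))
    w <- mu * (1 - mu)
    if (all(w < 1e-10))
      stop("perfect separation detected: fitted probabilities saturated",
           call. = FALSE)
    # weighted least squares step on the working response
    z <- eta + (y - mu) / pmax(w, 1e-10)
    fit <- stats::lm.wfit(X, z, w = pmax(w, 1e-10))
    beta_new <- fit$coefficients
    if (anyNA(beta_new))
      stop("rank-deficient design during IRLS", call. = FALSE)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (max(abs(beta)) > 30)
      stop("perfect separation detected: coefficients diverging", call. = FALSE)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  loglik <- c(loglik, sum(y * eta - log1p(exp(eta))))
  if (!converged && all(abs(y - mu) < 1e-3))
    stop("perfect separation detected: fitted probabilities saturated",
         call. = FALSE)
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  zstat <- beta / se
  zcrit <- stats::qnorm(0.975)
  structure(list(coefficients = beta, se = se,
                 or = exp(beta),
                 or_lo = exp(beta - zcrit * se),
                 or_hi = exp(beta + zcrit * se),
                 z = zstat,
                 p = 2 * stats::pnorm(-abs(zstat)),
                 converged = converged, iterations = iter,
                 loglik = loglik, n = n),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients, se = x$se, or = x$or,
                    or_lo = x$or_lo, or_hi = x$or_hi, p = x$p)
  print(round(tab, 4))
  cat(sprintf("n = %d; %sconverged in %d iterations; final log-lik %.4f\n",
              x$n, if (x$converged) "" else "NOT ", x$iterations,
              x$loglik[length(x$loglik)]))
  invisible(x)
}

#' Coefficient table of a logistic fit
#'
#' @param fit A `logistic_fit`.
#' @return Data frame with one row per coefficient: estimate, SE, odds ratio
#'   with 95% CI, z and p.
#' @export
logistic_summary <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se),
             or = unname(fit$or),
             or_lo = unname(fit$or_lo),
             or_hi = unname(fit$or_hi),
             z = unname(fit$z),
             p = unname(fit$p),
             row.names = NULL)
}
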
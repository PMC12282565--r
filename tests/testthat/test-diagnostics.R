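test_that("confusion_from_threshold counts every quadrant", {
  scores <- c(0, 1, 2, 3, 4, 5, 6, 4)
  outcome <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  conf <- confusion_from_threshold(scores, outcome, 4)
  expect_identical(unclass(conf)[c("tp", "fp", "fn", "tn")],
                   list(tp = 3L, fp = 1L, fn = 1L, tn = 3L))
  expect_identical(conf$tp + conf$fp + conf$fn + conf$tn, length(scores))
  # all-negative outcome and unreachable cutoff degenerate correctly
  none <- confusion_from_threshold(scores, rep(FALSE, 8), 4)
  expect_identical(c(none$tp, none$fn), c(0L, 0L))
  high <- confusion_from_threshold(scores, outcome, 99)
  expect_identical(c(high$tp, high$fp), c(0L, 0L))
  expect_error(confusion_from_threshold(numeric(0), logical(0), 1), "empty")
  expect_error(confusion_from_threshold(1:3, c(TRUE, FALSE), 1), "length")
  expect_error(confusion_from_threshold(c(1, NA), c(TRUE, FALSE), 1),
               "missing")
})

test_that("diagnostic metrics match hand arithmetic and flag undefined", {
  panel <- diagnostic_metrics(binary_confusion(33, 44, 64, 259))
  expect_equal(panel$sensitivity$estimate, 33 / 97)
  expect_equal(panel$specificity$estimate, 259 / 303)
  expect_equal(panel$ppv$estimate, 33 / 77)
  expect_equal(panel$npv$estimate, 259 / 323)
  expect_equal(panel$auc_binary,
               (panel$sensitivity$estimate + panel$specificity$estimate) / 2)
  # sensitivity * (tp+fn) = tp exactly
  expect_equal(panel$sensitivity$estimate * 97, 33)

  perfect <- diagnostic_metrics(binary_confusion(10, 0, 0, 10))
  expect_equal(vapply(perfect[c("sensitivity", "specificity", "ppv", "npv")],
                      function(m) m$estimate, numeric(1)),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  degen <- diagnostic_metrics(binary_confusion(0, 0, 5, 5))
  expect_equal(degen$sensitivity$estimate, 0)
  expect_true(is.na(degen$ppv$estimate))  # undefined, not silently 0
  expect_error(diagnostic_metrics(binary_confusion(0, 3, 0, 4)),
               "condition-positive")
})

test_that("binomial CIs bracket the estimate; exact CI matches binom.test", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:120, 1)
    x <- sample(0:n, 1)
    for (method in c("clopper_pearson", "wilson")) {
      ci <- proportion_ci(x, n, method)
      expect_lte(ci$lo, ci$estimate)
      expect_gte(ci$hi, ci$estimate)
      expect_true(ci$lo >= 0 && ci$hi <= 1)
    }
    # independent oracle for the exact interval
    bt <- stats::binom.test(x, n)
    cp <- proportion_ci(x, n, "clopper_pearson")
    expect_equal(c(cp$lo, cp$hi), as.numeric(bt$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("odds ratio matches the cross-product and handles zero cells", {
  or <- odds_ratio(binary_confusion(33, 44, 64, 259))
  expect_equal(or$or_estimate, (33 * 259) / (44 * 64))
  expect_false(or$continuity_corrected)
  expect_true(or$lo < or$or_estimate && or$or_estimate < or$hi)
  # no association: (a, b, a, b) gives OR 1
  expect_equal(odds_ratio(binary_confusion(7, 11, 7, 11))$or_estimate, 1)
  corrected <- odds_ratio(binary_confusion(1, 0, 1, 1))
  expect_true(corrected$continuity_corrected)
  expect_equal(corrected$or_estimate, (1.5 * 1.5) / (0.5 * 1.5))
  expect_error(odds_ratio(binary_confusion(0, 0, 3, 4)), "undefined")
})

test_that("pearson_correlation is exact on affine data and matches cor.test", {
  x <- c(1.2, 3.5, 2.2, 8, 5, 4.4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_correlation(x, -x)$r, -1.0)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    a <- rnorm(n); b <- 0.4 * a + rnorm(n)
    b[sample(n, sample(0:2, 1))] <- NA  # pairwise deletion path
    mine <- pearson_correlation(a, b)
    ct <- stats::cor.test(a, b, use = "complete.obs")
    expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mine$p_two_sided, ct$p.value, tolerance = 1e-12)
    expect_identical(mine$n, sum(stats::complete.cases(a, b)))
  }
  expect_error(pearson_correlation(x, rep(2, 6)), "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), "3 complete pairs")
})

test_that("group comparison: Fisher matches enumeration oracle, chi2 falls back", {
  # identical groups on a balanced 2x2: Fisher p = 1
  expect_equal(group_comparison(rbind(c(10, 10), c(10, 10)),
                                "fisher_exact")$p_two_sided, 1)
  set.seed(11)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 5) + 1, 2, 2)
    mine <- fisher_exact_p(tab)
    oracle <- stats::fisher.test(tab)$p.value
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
  # extreme table: p equals the explicit hypergeometric tail sum
  expect_equal(group_comparison(rbind(c(10, 0), c(0, 10)),
                                "fisher_exact")$p_two_sided,
               2 * stats::dhyper(10, 10, 10, 10), tolerance = 1e-12)
  # small expected counts force the flagged fallback
  small <- group_comparison(rbind(c(2, 1), c(1, 3)), "chi_square")
  expect_identical(small$test, "fisher_exact")
  expect_true(small$fallback)
  expect_error(group_comparison(rbind(c(0, 0), c(1, 2)), "chi_square"),
               "degenerate")
})

test_that("welch t and one-way ANOVA agree with stats::", {
  set.seed(3)
  a <- rnorm(40, 0); b <- rnorm(35, 0.2)
  w <- group_comparison(list(a, b), "welch_t")
  ref <- stats::t.test(a, b)
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$p_two_sided, ref$p.value)
  g3 <- list(rnorm(20), rnorm(20, 0.5), rnorm(20, 1))
  av <- group_comparison(g3, "one_way_anova")
  ref2 <- stats::oneway.test(
    unlist(g3) ~ factor(rep(1:3, each = 20)), var.equal = TRUE)
  expect_equal(av$p_two_sided, ref2$p.value)
  # equal-mean large samples: statistic near 0
  set.seed(4)
  big <- group_comparison(list(rnorm(5000), rnorm(5000)), "welch_t")
  expect_lt(abs(big$statistic), 3)
})

test_that("two-proportion power behaves like the closed form", {
  # null case: power equals the type-I rate
  expect_equal(two_proportion_power(0.3, 0.3, 100, 100), 0.05,
               tolerance = 0.002)
  expect_gt(two_proportion_power(0.207, 0.675, 323, 77), 0.99)
  # monotone in effect size and in n
  p_small <- two_proportion_power(0.3, 0.4, 100, 100)
  p_big <- two_proportion_power(0.3, 0.5, 100, 100)
  expect_gt(p_big, p_small)
  expect_gt(two_proportion_power(0.3, 0.4, 400, 400), p_small)
  expect_error(two_proportion_power(-0.1, 0.5, 50, 50), "proportions")
})

test_that("logistic IRLS: null fit, analytic 2x2 equivalence, diagnostics", {
  set.seed(5)
  n <- 800
  x <- rnorm(n)
  y <- runif(n) < 0.35  # independent of x
  fit <- logistic_irls(cbind(x = x), y)
  expect_true(fit$converged)
  expect_equal(fit$or[["x"]], 1, tolerance = 0.25)
  expect_equal(fit$coefficients[["(Intercept)"]], qlogis(mean(y)),
               tolerance = 0.2)
  # log-likelihood never decreases across iterations
  expect_true(all(diff(fit$loglik) > -1e-8))

  # single binary predictor: Wald OR equals the 2x2 odds ratio
  exposure <- rep(c(1, 0), times = c(120, 140))
  outc <- c(rep(c(TRUE, FALSE), times = c(45, 75)),
            rep(c(TRUE, FALSE), times = c(30, 110)))
  fit2 <- logistic_irls(cbind(exposure = exposure), outc)
  tab_or <- odds_ratio(binary_confusion(45, 75, 30, 110))
  expect_equal(fit2$or[["exposure"]], tab_or$or_estimate, tolerance = 1e-6)
  expect_equal(c(fit2$or_lo[["exposure"]], fit2$or_hi[["exposure"]]),
               c(tab_or$lo, tab_or$hi), tolerance = 1e-6)

  # agreement with glm on a multivariable fit
  set.seed(6)
  X <- cbind(a = rnorm(500), b = rbinom(500, 1, 0.4))
  yy <- runif(500) < plogis(-1 + 0.8 * X[, "a"] - 0.5 * X[, "b"])
  mine <- logistic_irls(X, yy)
  ref <- stats::glm(yy ~ X, family = stats::binomial())
  expect_equal(unname(mine$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)

  # explicit failures
  expect_error(logistic_irls(cbind(x = c(x, 1)), c(y, 2)), "binary")
  expect_error(logistic_irls(cbind(a = 1:20, b = 2 * (1:20)),
                             rep(c(TRUE, FALSE), 10)), "rank-deficient")
  sep_x <- c(rnorm(20, -3), rnorm(20, 3))
  sep_y <- rep(c(FALSE, TRUE), each = 20)
  expect_error(logistic_irls(cbind(x = sep_x), sep_y), "separation")
})
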
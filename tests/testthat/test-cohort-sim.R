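test_that("the built-in fixture reproduces every printed marginal", {
  spec <- table1_fixture()
  expect_identical(sum(spec$group_sizes), 400L)
  expect_identical(spec$group_sizes, c(82L, 125L, 72L, 44L, 41L, 25L, 11L))
  expect_identical(sum(spec$transfusion), 119L)
  expect_identical(sum(spec$mtp), 13L)
  expect_identical(sum(spec$mortality), 10L)
  expect_identical(sum(spec$laparotomy), 78L)
  # surgical intervention (incl. surgical-plus-IR) totals 97
  expect_identical(sum(spec$management["surgical", ] +
                         spec$management["surgical_plus_ir", ]), 97L)
  expect_identical(as.integer(colSums(spec$management)), spec$group_sizes)
})

test_that("fixture expansion round-trips through the scoring module", {
  cohort <- expand_fixture(table1_fixture())
  expect_identical(nrow(cohort), 400L)
  scored <- score_cohort(cohort)
  expect_identical(as.integer(table(scored$fasila_total)),
                   table1_fixture()$group_sizes)
  expect_identical(sum(scored$fasila_total >= 4), 77L)
  # per-score outcome counts all match the spec
  spec <- table1_fixture()
  for (s in 0:6) {
    lvl <- scored[scored$fasila_total == s, ]
    expect_identical(sum(outcome_vector(lvl, "transfusion")),
                     spec$transfusion[s + 1])
    expect_identical(sum(outcome_vector(lvl, "mtp")), spec$mtp[s + 1])
    expect_identical(sum(outcome_vector(lvl, "laparotomy")),
                     spec$laparotomy[s + 1])
    expect_identical(sum(outcome_vector(lvl, "mortality")),
                     spec$mortality[s + 1])
    expect_identical(sum(outcome_vector(lvl, "surgery")),
                     unname(spec$management["surgical", s + 1] +
                              spec$management["surgical_plus_ir", s + 1]))
  }
  validate_cohort(cohort)  # includes the mtp -> blood_units >= 10 invariant
})

test_that("fixture expansion is deterministic down to the byte", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(expand_fixture(table1_fixture()), f1)
  write_cohort_csv(expand_fixture(table1_fixture()), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("fixture spec validates its invariants and serializes", {
  spec <- table1_fixture()
  expect_error(fixture_spec(spec$group_sizes, spec$management,
                            spec$laparotomy, spec$transfusion,
                            mtp = spec$group_sizes + 1L,
                            mortality = spec$mortality),
               "bounded")
  bad_mgmt <- spec$management; bad_mgmt[1, 1] <- bad_mgmt[1, 1] + 1L
  expect_error(fixture_spec(spec$group_sizes, bad_mgmt, spec$laparotomy,
                            spec$transfusion, spec$mtp, spec$mortality),
               "sum to group_sizes")
  path <- tempfile(fileext = ".json")
  write_fixture_spec(spec, path)
  back <- read_fixture_spec(path)
  expect_identical(back$group_sizes, spec$group_sizes)
  expect_identical(back$management, spec$management)
  # all-zero spec expands to an empty cohort
  zero <- fixture_spec(rep(0L, 7),
                       matrix(0L, 5, 7,
                              dimnames = list(rownames(spec$management),
                                              NULL)),
                       rep(0L, 7), rep(0L, 7), rep(0L, 7), rep(0L, 7))
  expect_identical(nrow(expand_fixture(zero)), 0L)
})

test_that("simulation is seed-reproducible and config-validated", {
  cfg <- cohort_config(n = 150)
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a, c))
  expect_identical(nrow(simulate_cohort(cohort_config(n = 0), seed = 1)), 0L)
  expect_error(cohort_config(penetrating_prob = 1.5), "penetrating_prob")
  expect_error(cohort_config(hr_bounds = c(5, 180)), "hr_bounds")
  expect_error(cohort_config(ais_probs = c(0.5, 0.5, 0.5)), "ais_probs")
  path <- tempfile(fileext = ".json")
  write_cohort_config(cfg, path)
  expect_identical(read_cohort_config(path)$n, 150L)
})

test_that("simulated cohorts carry the configured statistical structure", {
  cohort <- simulate_cohort(cohort_config(n = 5000), seed = 12)
  scored <- score_cohort(cohort, check_range = FALSE)
  # scores concentrate at the low end
  expect_gt(mean(scored$fasila_total <= 2), 0.5)
  # strong positive score / systolic-SI coupling
  expect_gt(pearson_correlation(scored$fasila_total,
                                scored$systolic_si)$r, 0.5)
  # severity couplings carry the configured signs
  expect_gt(pearson_correlation(scored$fasila_total, scored$iss)$r, 0)
  expect_gt(pearson_correlation(scored$fasila_total, scored$sofa)$r, 0)
  expect_lt(pearson_correlation(scored$fasila_total, scored$fibrinogen)$r, 0)
  # empirical transfusion prevalence within 3 Monte-Carlo SE of the
  # model-implied mean for this cohort's realized scores
  model <- cohort_config()$outcome_models$transfusion
  p <- plogis(model[1] + model[2] * scored$fasila_total)
  se <- sqrt(sum(p * (1 - p))) / nrow(scored)
  expect_lt(abs(mean(scored$transfused) - mean(p)), 3 * se + 0.01)
  # monotone outcome prevalence in score (pooled top levels are sparse)
  prev <- tapply(scored$transfused, pmin(scored$fasila_total, 5), mean)
  expect_true(all(diff(prev) > 0))
  validate_cohort(cohort)
})

test_that("a zero outcome slope severs the score-outcome link", {
  cfg <- cohort_config(n = 4000, outcome_models = list(
    transfusion = c(-1.2, 0), mtp = c(-7.5, 0), surgery = c(-2.2, 0.4),
    laparotomy = c(-2.3, 0.4), mortality = c(-4.3, 0.35)))
  scored <- score_cohort(simulate_cohort(cfg, seed = 3), check_range = FALSE)
  # prevalence flat in score: chi-square across levels non-significant
  tab <- table(pmin(scored$fasila_total, 4), scored$transfused)
  p <- group_comparison(as.matrix(tab), "chi_square")$p_two_sided
  expect_gt(p, 0.01)
  # transfusion is the union with MTP, so the implied marginal is
  # 1 - (1-p_tx)(1-p_mtp); allow a 4-SE Monte-Carlo band
  target <- 1 - (1 - plogis(-1.2)) * (1 - plogis(-7.5))
  mc_se <- sqrt(target * (1 - target) / nrow(scored))
  expect_lt(abs(mean(scored$transfused) - target), 4 * mc_se)
})
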
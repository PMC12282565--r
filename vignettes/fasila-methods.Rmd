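---
title: "Methods: the FASILA score, its validation statistics, and the cohort generators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the FASILA score, its validation statistics, and the cohort generators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasila)
```

## The score and its assumptions

FASILA is an additive 0–6 triage score for adult abdominopelvic trauma,
summing a FAST ultrasound point (0/1), systolic shock-index points (0–3)
and serum-lactate points (0–2). All three inputs are available within
minutes of arrival; the score deliberately excludes anything requiring
imaging interpretation or registry lookup. The package treats registry
severity measures (ISS, AIS, GCS, RTS, TRISS, SOFA) as pass-through fields:
computing them from raw injury data is out of scope.

Component binning follows the published definitions, with three edge
policies this package had to decide:

* **Shock index below 0.50.** The published lowest bin starts at 0.50. We
  assign 0 points to any SI below 0.70, including SI < 0.50: a lower shock
  index is physiologically *less* shocked, so the least-points assignment
  is the only defensible extension, and it keeps the score defined for all
  valid vitals.
* **Bin boundaries.** The outer bins carry explicit ≤/≥ qualifiers
  (lactate "≤ 2.0" and "≥ 4.0"), so those win at shared endpoints: lactate
  exactly 2.0 scores 0 and exactly 4.0 scores 2; the middle band is open at
  both ends. SI bins are half-open on the right with the top bin closed
  below at 0.90. This is the only reading that makes the bins a partition.
* **Indeterminate FAST.** The score was never defined for inconclusive
  scans. The default policy is a hard "unscorable" error; callers may
  choose to score indeterminate as negative or positive, or (as the cohort
  pipeline does) to flag the row and continue. Flagged rows are excluded
  from evaluation with a logged count, never silently imputed.

Vitals outside sanity bounds (HR 20–250 beats/min, SBP 40–300 mmHg) trigger
a warning rather than an error — they are usually unit mistakes in CSV
input, and the warning can be disabled once the data are known clean.

Totals are dichotomised at a cutoff of 4 (low < 4, high ≥ 4), exposed as a
parameter. The source analyses once write "> 4" in the regression figure
while using ≥ 4 everywhere else; we standardise on ≥ 4 for all dichotomies
and keep the regression on the *continuous* 0–6 total, so the package never
has to guess which dichotomy the original regression used.

## Evaluation statistics

* **Diagnostic panel.** Sensitivity, specificity, PPV and NPV from the 2×2
  at a threshold, each with a binomial CI. The original tables do not name
  a CI method; Clopper–Pearson exact is the default (it never undercovers),
  Wilson is selectable. Point estimates, not CIs, are the reproduction
  surface. A zero denominator leaves that metric `NA` ("undefined"), never
  silently 0. Percentages are reported at 1 decimal, AUROC at 2, matching
  the source presentation.
* **AUROC.** With a 7-level score, ties dominate; the implementation is the
  tie-aware Mann–Whitney estimator (midranks), which equals trapezoidal
  integration through tied groups and is checked in the suite against an
  exhaustive positive×negative pairwise oracle. Two AUROCs are reported for
  a thresholded test and labelled distinctly: the binary-test value
  (sens + spec)/2 and the continuous-score value, because the source table
  prints the latter (0.7) next to binary metrics whose implied area is 0.60.
* **Curve comparison.** No comparison method is stated in the source; we
  use a stratified patient bootstrap (cases and controls resampled
  separately, both scores recomputed per replicate, percentile CI on the
  difference), seeded and reproducible. A parametric correlated-AUC test
  would need distributional assumptions the ordinal scores do not meet.
* **Odds ratios** use the cross-product with a Woolf log-scale CI, applying
  the Haldane–Anscombe +0.5 correction only when a cell is zero (flagged);
  two zeros in one margin leave the OR undefined, as an error.
* **Fisher's exact test** is computed in-package by full hypergeometric
  enumeration (sum of all tables as or less probable than the observed one,
  with a 1e-7 relative guard for floating-point ties); a chi-square request
  falls back to Fisher, flagged, when any expected cell is below 5.
* **Logistic regression** is iteratively reweighted least squares with Wald
  odds ratios. Convergence is the max coefficient change < 1e-8 within 100
  iterations; rank deficiency and perfect separation (diverging
  coefficients or saturated fitted probabilities) are explicit errors. The
  transfusion model adjusts the FASILA total for abdominal AIS, ISS, SOFA
  and fibrinogen — the score's own components (SI, lactate, FAST) are
  excluded as adjusters because they are part of the exposure. Missing
  covariates are dropped listwise with a logged count; correlations use
  pairwise deletion (the source correlation table prints a different N per
  pair).
* **Post-hoc power** uses the standard two-proportion z formulation: pooled
  SE under the null, unpooled under the alternative, two-sided alpha 0.05.
  The source prints a power of 97.63% that cannot be recovered from any
  pair of printed proportions (the transfusion proportions 20.7% vs 67.5%
  at 323/77 give power ≈ 1); the operation implements the formula and makes
  no claim to reproduce that figure.
* **Multiple testing.** The source applies no correction; none is applied.

## The deterministic fixture

`table1_fixture()` carries the printed per-score marginals of the
400-patient validation cohort: group sizes 82/125/72/44/41/25/11 and
per-score counts for the five management categories, exploratory
laparotomy, transfusion, MTP and mortality. `expand_fixture()` turns them
into patient-level rows:

* Each score level gets the **canonical component decomposition** —
  SI points filled first, then lactate, then FAST (so total 3 is SI 3,
  lactate 0, FAST negative; total 6 is the only level with positive FAST).
  Only the total is constrained by the printed tables, so a convention was
  needed; this one concentrates variation in the component with the most
  levels and is configurable in principle via a custom `fixture_spec`.
* Vitals are **back-solved bin representatives** (SBP 100 with HR
  60/75/85/100; lactate 1.5/3.0/4.5), with jitter deliberately disabled so
  expansion is byte-identical across runs and re-scoring round-trips
  exactly.
* Outcome flags go to the **first k records** of each score level, with
  management laid out surgical-first so laparotomy and transfusion overlap
  the operative records, and MTP nested inside transfusion (the protocol
  implies transfusion; MTP records receive 12 units, other transfused
  records 3, satisfying the ≥ 10-unit MTP invariant). Every per-outcome,
  per-score analysis therefore matches the printed counts exactly, while
  joint cross-tabulations between outcomes are explicitly *not* claimed to
  match the source cohort.
* Continuous covariates (age, ISS, SOFA, AIS, RTS, TRISS, fibrinogen, LOS)
  are filled from per-stratum summary statistics and are reconstructions,
  not data. Two consequences matter: the multivariable regression is
  degenerate on the fixture (covariates are constant within score levels —
  the report says so rather than failing), and between-group tests on those
  covariates have artificially small variance. The fixture's purpose is the
  score/outcome analyses, which depend only on counts. Likewise the
  fixture's diastolic SI is constant per SI bin (HR/60), so the
  "diastolic SI > 2.2" panel on the fixture is degenerate (no positives) —
  honest, since the printed vitals do not constrain patient-level DBP.

What a green fixture test establishes: the scoring and diagnostic code
reproduce the published counts, panel and AUROC from first principles. What
it does not establish: anything about covariate-level structure, which only
the simulator exercises.

## The stochastic simulator

`simulate_cohort()` draws seeded synthetic cohorts with the structure the
analysis assumes, for power/property testing — it is a stand-in, not a
generative model of the registry. Defaults state the emulated world once:
400 patients, 96% blunt, 90% male, age 36.3 ± 12.7 (the published
demographics); HR ~ N(85, 20) on [40, 180] and SBP ~ N(122, 18) on
[70, 220] (truncated normals via inverse-CDF, chosen so the systolic SI
distribution centres near 0.7 and yields the low-score-heavy FASILA
distribution); DBP as a N(0.60, 0.06) fraction of SBP; lactate lognormal
with location increasing in SI (slope 0.9 — shock drives lactate); FAST
positivity logistic in abdominal AIS; each outcome Bernoulli with logit
linear in the FASILA total, intercepts/slopes set so prevalences rise from
roughly the published score-0 rates to the score-6 rates (transfusion
−2.6 + 0.75·score; MTP −7.5 + 1.2·score; surgery −2.2 + 0.4·score;
mortality −4.3 + 0.35·score); ISS and SOFA increase and fibrinogen
decreases in the score. MTP implies transfusion and ≥ 10 units by
construction. Features of real data the simulator does not emulate:
inter-component correlation beyond the SI→lactate and AIS→FAST links,
missingness, multi-site heterogeneity, and length-of-stay tails.

## Numerical choices and degenerate inputs

Ties in the ROC use midranks exactly (no epsilon jitter). The strict
threshold tests "systolic SI > 0.80" and "diastolic SI > 2.2" are
implemented as `score >= cutoff + 1e-9` to express strict inequality on
floating-point ratios. Bootstrap percentile intervals use quantile type 7.
The IRLS working weights are floored at 1e-10 to keep the weighted solve
finite near saturation; separation is declared when coefficients pass ±30
or the fit saturates without converging. Single-class outcomes, empty
confusion margins, zero-variance correlations and degenerate contingency
tables are all explicit errors with named causes, mapped by the CLI to exit
code 3 (statistical degeneracy) versus 2 (schema errors).

## Known limitations

The fixture reproduces printed marginals only; its covariates cannot
support the multivariable regression, and the published whole-cohort AUROCs
for MTP (0.96) and any transfusion (0.77) differ from the count-derived
values here (0.97, 0.76) by about 0.01, consistent with undocumented
missing-data exclusions in the source — the pipeline reports these numbers
for comparison but the package does not assert them. The published PPV of
42.8% appears to truncate 33/77 = 42.857%, which rounds to 42.9 at one
decimal. The post-hoc power figure of 97.63% is not reproducible from any
printed inputs.
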
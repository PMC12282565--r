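# fasila

Bedside triage scoring and diagnostic-accuracy validation for abdominal and
pelvic trauma.

## The problem

During initial trauma resuscitation the clinician must decide, within
minutes and with incomplete information, whether a patient with
abdominopelvic injuries is likely to need blood, massive transfusion or
surgery. The FASILA score is an additive 0–6 bedside score built from three
parameters available at the door:

    FASILA = FAST + SI points + lactate points

* **FAST** (focused assessment with sonography in trauma): negative = 0,
  positive = 1;
* **SI points** from the systolic shock index SI = HR / SBP:
  0 for SI < 0.70, 1 for [0.70, 0.80), 2 for [0.80, 0.90), 3 for ≥ 0.90;
* **lactate points** from initial serum lactate:
  0 for ≤ 2.0 mmol/L, 1 for 2.0–4.0 mmol/L, 2 for ≥ 4.0 mmol/L.

Totals are dichotomised into low (< 4) and high (≥ 4) risk. This package
implements the score, its comparators (ABC score, systolic and diastolic
shock index), and the complete evaluation pipeline used to validate such
scores: confusion tables, sensitivity/specificity/PPV/NPV with
Clopper–Pearson or Wilson intervals, tie-aware Mann–Whitney ROC/AUROC with
stratified-bootstrap curve comparison, odds ratios (Woolf CI,
Haldane–Anscombe correction), Pearson correlations, chi-square / Fisher /
Welch / one-way ANOVA group comparisons, logistic regression by IRLS, and
two-proportion post-hoc power. It is aimed at trauma researchers validating
triage scores on registry cohorts, and at methodologists who need a
reproducible reconstruction of the published validation analyses.

Two data sources are built in:

* `table1_fixture()` / `expand_fixture()` — a deterministic, patient-level
  reconstruction of a published 400-patient validation cohort from its
  printed per-score counts (score distribution 82/125/72/44/41/25/11;
  119 transfused; 13 MTP activations; 10 deaths). Only per-score,
  per-outcome marginals are constrained; joint cross-tabulations and the
  continuous covariate fills are reconstructions, not data.
* `simulate_cohort()` — a seeded stochastic simulator of blunt-dominant
  abdominopelvic trauma cohorts with the couplings the analysis assumes.

## Worked example

```r
library(fasila)

cohort <- expand_fixture(table1_fixture())   # 400 patient-level records
scored <- score_cohort(cohort)               # FASILA, ABC, shock indices
surgery <- outcome_vector(scored, "surgery") # surgical or surgical-plus-IR

conf <- confusion_from_threshold(scored$fasila_total, surgery, 4)
diagnostic_metrics(conf)
```

```
Sensitivity: 34.0% (24.7%-44.3%)
Specificity: 85.5% (81.0%-89.2%)
PPV:         42.9% (31.6%-54.6%)
NPV:         80.2% (75.4%-84.4%)
Binary-test AUROC (sens+spec)/2: 0.60
```

High specificity and NPV at the cutoff of 4: a low FASILA score identifies
patients unlikely to need surgery. The continuous score discriminates
better than the dichotomised test:

```r
auroc_mann_whitney(scored$fasila_total, surgery)
```

```
ROC curve: 97 positives, 303 negatives, 8 operating points
AUROC (tie-aware Mann-Whitney): 0.6868
```

The full report (group comparison, correlation panel, diagnostic panels at
FASILA ≥ 4 / systolic SI > 0.80 / diastolic SI > 2.2, AUROC comparison
against the ABC score, transfusion regression, post-hoc power):

```r
report <- evaluate_cohort(scored, n_boot = 2000, seed = 1)
print(report)
```

## Command line

```sh
Rscript inst/cli/fasila simulate --output cohort.csv --fixture table1
Rscript inst/cli/fasila score    --input cohort.csv --output scored.csv
Rscript inst/cli/fasila evaluate --input scored.csv --out-dir results/
# or score + evaluate in one step:
Rscript inst/cli/fasila report   --input cohort.csv --out-dir results/
```

Outputs: `report.json` (machine-readable, deterministic), `report.txt`
(formatted tables), ROC coordinate CSVs, and a provenance JSON recording
the seed and package version. Exit codes: 0 success, 2 schema error,
3 statistical degeneracy.

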
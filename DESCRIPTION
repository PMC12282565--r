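Package: fasila
Title: FASILA Bedside Triage Score and Diagnostic-Accuracy Validation for
    Abdominopelvic Trauma
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the FASILA bedside triage score (FAST ultrasound,
    shock index, serum lactate; range 0-6) for abdominal and pelvic trauma,
    together with the comparator scores (ABC, systolic and diastolic shock
    index) and a complete diagnostic-accuracy toolkit: confusion tables,
    sensitivity/specificity/PPV/NPV with exact or Wilson confidence
    intervals, tie-aware Mann-Whitney ROC/AUROC with stratified bootstrap
    comparison, odds ratios, Pearson correlations, group-comparison tests,
    logistic regression by iteratively reweighted least squares, and
    two-proportion power. Includes a deterministic fixture that expands a
    published 400-patient cohort's printed per-score counts into
    patient-level records, a seeded stochastic cohort simulator, and a
    command-line pipeline (score, evaluate, simulate) over a documented
    cohort CSV schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
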
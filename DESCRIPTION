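Package: hemoscore
Title: Clinical Scores and Diagnostic Accuracy Analysis for Massive
    Transfusion Prediction in Trauma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calculators for six clinical scores used to predict the need
    for massive transfusion in severely injured trauma patients (mTICCS,
    TASH, ABC, Larson, PWH, ETS), driven by an auditable JSON rubric
    configuration, together with the full diagnostic-accuracy workflow:
    empirical ROC curves, AUC with DeLong confidence intervals, paired
    DeLong comparison of correlated AUCs, Youden-index cut-off selection,
    and confusion-matrix metrics (sensitivity, specificity, PPV, NPV,
    prevalence) with exact Clopper-Pearson and Mercaldo logit confidence
    intervals. Includes median/range and frequency group descriptives with
    Wilcoxon rank-sum and chi-square tests, a seedable synthetic
    trauma-cohort generator with a latent severity factor, and an
    end-to-end validation pipeline with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
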
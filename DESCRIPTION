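Package: lipicourse
Title: Longitudinal Serum Lipidome Time-Course Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Lifetime-aligned analysis of longitudinal LC-MS serum lipidomics
    cohorts, built around a Dicer1-Pten double-knock-out (DKO) mouse model of
    high-grade serous ovarian carcinoma. Provides feature-table ingestion with
    blank, QC-presence and QC-RSD curation filters and cubic-spline signal
    drift correction; lipid shorthand to elemental formula, adduct m/z and
    ppm mass-error arithmetic; percentage-lifetime alignment into five
    lifetime stages; stage-resolved Welch/Benjamini-Hochberg differential
    statistics with upset-style intersection logic; fold-change trajectory
    clustering with correlation distance and complete linkage plus Pearson
    correlation networks; per-stage classification (logistic regression,
    random forest, RBF support vector machine, k-nearest-neighbors, soft
    voting) with Gini-importance feature selection, ROC-AUC evaluation and
    permutation validation; Kaplan-Meier, Nelson-Aalen, log-rank and
    restricted-mean-survival-time prognostic lipid screening; and a synthetic
    cohort generator with ground-truth recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    e1071,
    class,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
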
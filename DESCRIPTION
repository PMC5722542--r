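Package: pgxmarkers
Title: Comparing Single-Gene and Multi-Gene Markers of Cancer Drug Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the systematic comparison of single-gene drug-sensitivity
    markers against multi-gene random-forest classifiers on release-versioned
    (time-stamped) pharmacogenomic screens. Provides a reader/writer for the
    GDSC-style CSV dialect with 'x::y' mutation annotations, a synthetic cohort
    generator with planted driver genes, per-drug time-stamped train/test
    partitioning with median-threshold sensitivity labels, univariate drug-gene
    association testing with Benjamini-Hochberg correction, random-forest
    training with mtry selection by stratified cross-validation, and
    confusion-matrix metrics (MCC, precision, recall, F1) with the degenerate-case
    conventions used in prospective biomarker evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
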
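Package: immunofrail
Title: Synthetic Immune Cellular Profiling and Frailty Association Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the relationship between frailty and the
    composition of leukocyte subpopulations in peripheral blood of older
    adults. Provides a synthetic-data generator for two-tube flow-cytometry
    event data and cohort metadata with a calibrated rank-correlation
    structure, hierarchical gating of 37 leukocyte subpopulations, absolute
    cell enumeration by bead-based (TruCOUNT-style) arithmetic with
    cross-tube CD3 scaling, a 36-deficit Rockwood frailty index,
    mixture-model cytomegalovirus serostatus classification, sex-stratified
    blocked permutation association tests with a block-weighted Spearman
    statistic and Benjamini-Hochberg control, and random-forest prediction
    of frailty with permutation importance and partial dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
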
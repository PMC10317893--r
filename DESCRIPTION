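Package: tgtree
Title: Postoperative Thyroglobulin Decision-Tree Risk Model for Thyroid Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conditional inference trees for predicting a positive
    post-treatment whole-body scintigraphy (PT-WBS) in differentiated
    thyroid cancer from postoperative thyroglobulin and clinical staging.
    Implements the permutation-framework association tests, cutpoint
    search and significance-based stopping of the conditional inference
    tree algorithm for a binary endpoint; stability-based variable
    selection over stratified bootstrap resamples; repeated stratified
    Monte Carlo cross-validation with node-threshold aggregation; the
    published five-node risk calculator; and a calibrated synthetic
    cohort generator with a planted piecewise outcome model for
    end-to-end testing and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
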
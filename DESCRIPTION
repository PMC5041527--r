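Package: ewascreen
Title: Environment-Wide Association Screening for Matched Case-Control
    Questionnaire Studies
Version: 0.1.0
Authors@R: person("Isis-Diab", "Analysis Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for environment-wide association studies
    (EWAS) on large mixed binary/ordinal questionnaires collected in
    matched case-control designs. Provides questionnaire encoding to the
    unit interval, a staged participant exclusion cascade, a matched
    stratified analysis (Cochran-Mantel-Haenszel tests and conditional
    logistic regression over matched sets), a propensity-score stratified
    analysis driven by out-of-bag random-forest predictions, dual
    multiple-testing discovery rules (family-wise error rate and false
    discovery rate), and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
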
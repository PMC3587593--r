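Package: occufit
Title: Single-Season Site-Occupancy Models for Replicated Detection Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits single-season site-occupancy models to replicated
    detection/non-detection surveys using the zero-inflated binomial
    likelihood with logit-linked site covariates, and supports the full
    workflow around them: AICc multimodel ranking with Akaike weights,
    naive-occupancy summaries, rank-based ROC/AUC evaluation, projection
    of occupied area from habitat extents, and a synthetic survey
    generator for design and recovery studies. Motivated by urban
    surveys of an invasive marsupial across stratified habitat types
    with a small number of exchangeable replicate detectors per site.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
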
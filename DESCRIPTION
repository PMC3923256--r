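Package: simcal
Title: Calibrating 2D Fingerprint Similarity Against Expert Judgments of
    Molecular Similarity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating computed 2D-fingerprint Tanimoto similarity
    of molecule pairs to expert-panel judgments of structural similarity.
    Implements several open 2D fingerprint schemes (circular, path-hashed,
    structural keys, hashed atom-pair keys), logistic calibration of the
    probability that an expert majority calls a pair similar, goodness-of-fit
    diagnostics (Nagelkerke R-squared, Hosmer-Lemeshow), ROC-based operating
    threshold selection with a full set of confusion-matrix statistics,
    multi-fingerprint consensus classification, and a synthetic expert-panel
    generator for end-to-end validation without proprietary data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    withr,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
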
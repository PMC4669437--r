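Package: dnfold
Title: Protein Fold Recognition with RBM-Pretrained Deep Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Template-based protein fold recognition from pairwise
    query-template similarity features. Implements restricted Boltzmann
    machine (RBM) pretraining with contrastive divergence, supervised
    fine-tuning of a sigmoid deep network classifier, a rectified-linear
    network for TM-score regression, AUC-ranked ensembling of an
    architecture pool, a score-sum meta-combiner, and the Lindahl-style
    benchmark protocol (query-grouped cross-validation with template
    removal, per-level Top-1/Top-5 success rates, specificity-sensitivity
    curves). A seeded generator of SCOP-like domain hierarchies, pairwise
    features and TM-score-like similarities makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
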
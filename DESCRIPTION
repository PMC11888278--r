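Package: ndclock
Title: Meta-Analytic Transcriptomic and Compositional Clocks for Neurodevelopmental Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting neurodevelopmental age (in gestational weeks)
    from single-cell transcriptomes across heterogeneous studies. Implements
    pseudo-bulk aggregation, log and rank normalization, cell-class composition
    tables, study-specific and meta-analytic compositional age models, PCA-based
    age projection, sparse elastic-net transcriptomic clocks (cell-type-specific
    and cell-type-agnostic with equal cell-type weighting) under leave-study-out
    and leave-cell-type-out cross-validation, aggregate rank-standardized
    co-expression networks with module clustering and enrichment, gene-set
    restricted model screens, cross-species ortholog-restricted prediction with
    developmental tempo estimation, and a multi-study synthetic cohort generator
    used to exercise every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
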
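Package: metasig
Title: Expression-Signature Discovery and Metastasis Stratification for
    Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for deriving a compact metastasis-
    stratifying gene signature from transcription-factor target gene lists
    in bulk expression cohorts. Implements gene-list intersection with
    direction concordance, quantile normalization and per-gene
    standardization, PCA-loading-based greedy backward elimination of a
    candidate panel under a variance-explained constraint, stepwise-AIC
    logistic stratification with ROC threshold optimization and
    cross-cohort transfer evaluation, Kaplan-Meier/log-rank/Cox survival
    association with backward selection, phenotype-permutation gene-set
    enrichment, and a seeded synthetic-cohort generator that emulates the
    primary/metastatic study design so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
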
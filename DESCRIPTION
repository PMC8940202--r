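Package: cohortharmony
Title: Curation, Ontology-Driven Harmonization and Incremental Federated
    Learning for Heterogeneous Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for preparing structurally heterogeneous clinical cohort
    tables for joint analysis and for training disease-prediction models
    across them without pooling patient-level data.  Provides automated data
    curation (inconsistent, duplicated and uninformative features, outlier
    cells, missing-value imputation with a replayable action log), a
    JSON-serialized disease reference model with a synonym-enriched medical
    corpus, lexical and semantic column-to-term matching with value
    standardization, a principal-component rank-sum consistency check of the
    harmonized cohorts, incremental (batch-wise) training of five classifier
    families across private data partitions with age- and sex-matched
    case-control downsampling and leave-one-cohort-out evaluation, rule
    extraction from the boosted-tree model, and a synthetic multi-cohort
    generator with known ground truth emulating a rare-outcome (lymphoma in
    primary Sjogren's Syndrome) setting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    rpart,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
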
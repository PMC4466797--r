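Package: BioassayTriage
Title: Cost-Sensitive Machine-Learning Triage of Imbalanced High-Throughput Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual-screening triage funnel for severely imbalanced
    single-concentration bioassays: activity labelling at an inhibition
    threshold, 2D molecular descriptors in three families (pharmacophore-pair
    fingerprints, Burden-eigenvalue descriptors, property descriptors),
    near-constant descriptor removal, correlation-based feature-subset
    selection with best-first search, cost-sensitive classification with a
    false-negative cost escalated against a false-positive-rate ceiling,
    confusion-matrix/G-mean/ROC evaluation, multi-model consensus prediction,
    SMARTS structural-alert and Lipinski filtering, and substructure-fragment
    enrichment analysis. Includes a synthetic compound-library generator with
    planted, substructure-driven activity signal so the whole funnel is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    ranger,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
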
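Package: mdvote
Title: Weighted-Voting Prediction of miRNA-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a sparse
    binary association network by weighted voting of the known associations.
    Builds a credibility similarity from the association matrix itself,
    integrates it with externally supplied miRNA functional similarity and
    disease semantic similarity (computed from ontology ancestor graphs),
    sparsifies each similarity row with an adaptive filter, and scores every
    pair with a three-factor vote weight (fairness normalisation, group
    influence, voter-candidate similarity).  Includes five-fold and global
    leave-one-out cross-validation with rank-based AUC, a hyperparameter
    sweep, and a seeded synthetic-network generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
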
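Package: multifuse
Title: Sparse Multimodal Data Fusion for Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fusing multiple patient-level data modalities
    (clinical variables, laboratory results, imaging-derived features and
    viral-genome mutation encodings). Implements penalized-matrix-
    decomposition sparse canonical correlation analysis for two or more
    views with permutation-based sparsity tuning, cooperative learning
    (multi-view elastic-net regression with an agreement penalty spanning
    early to late fusion) for continuous and binary outcomes, repeated
    stratified nested cross-validation, skip-gram embeddings of
    amino-acid mutation tokens with strain-level mean vectors and
    multidimensional-scaling projection, cohort descriptive tables with
    the matching two-group tests, and seeded synthetic-data generators
    that emulate the multi-view, phylogenetic and cohort structure of
    such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
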
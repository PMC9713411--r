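Package: mbcoin
Title: Multi-Block Co-Inertia Integration of Multi-Omics Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous, unsupervised integration of multi-omics,
    multi-compartment feature matrices (small RNA counts and methylation
    beta values measured on the same individuals) by multiple co-inertia
    analysis (MCIA), a multi-block latent-variable decomposition with
    block-loading deflation. Provides per-assay feature filtering and TMM
    normalization, projection of held-out samples onto the fitted latent
    space, clustering-derived ROC/AUC evaluation of latent variables,
    Lasso-based feature reduction with reduced-model refitting, and a
    synthetic cohort generator with a planted group-separating factor for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    edgeR,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
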
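Package: stagenet
Title: Stage-Associated Gene Coexpression Network Analysis and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering tumor-stage-associated gene
    signatures from multi-batch expression data: empirical-Bayes batch
    adjustment, SVD steady-state and variance filtering, moderated-t
    differential expression, signed weighted coexpression network
    construction with topological overlap, module eigengene and
    module-trait statistics, permutation Z-summary module preservation,
    network attack robustness (R- and V-indices), GS/K hub-gene calling,
    bootstrap elastic-net feature selection, and early-versus-late stage
    classification with cross-validated ROC/AUC. Includes a seeded
    synthetic-data generator that emulates the statistical structure of
    merged tumor/normal microarray compendia with planted coexpression
    modules, hubs and batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
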
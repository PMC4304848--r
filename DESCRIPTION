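Package: quadpot
Title: Four-Body Statistical Potentials and Tessellation-Based
    Computational Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives knowledge-based four-body statistical potentials from
    Delaunay tessellations of C-alpha coarse-grained protein structures,
    scores single-residue variants by environmental perturbation and
    residual profiles, assembles tessellation-derived feature vectors for
    variant-effect classification, and provides the accompanying
    structure-function statistics, cross-validated machine-learning
    models, and synthetic-data generators. The tessellation engine is an
    incremental Bowyer-Watson Delaunay triangulation with a 12 Angstrom
    edge-length filter for excluding spurious surface contacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    ggplot2,
    generics,
    bio3d,
    randomForest,
    e1071,
    rpart,
    nnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
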
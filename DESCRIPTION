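Package: gblupsel
Title: Low-Density SNP Panel Selection by Tree Ensembles with GBLUP Validation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building low-density SNP panels for genomic prediction
    in livestock. Per-SNP variable importance is computed with three tree
    ensembles implemented from first principles (random forest permutation
    importance, least-squares gradient boosting relative influence, and
    second-order regularized boosting gain). Candidate panels (top-k,
    positive-importance, evenly spaced baselines) are validated by GBLUP: a
    VanRaden genomic relationship matrix, restricted maximum likelihood
    variance components via the eigendecomposition of the relationship
    matrix, genomic breeding value prediction for unphenotyped animals, and
    k-fold cross-validated prediction accuracy. A synthetic cattle-like
    cohort generator with known QTLs, contemporary-group and age fixed
    effects, and a target genomic heritability supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
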
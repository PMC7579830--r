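Package: metamir
Title: Meta-Path Fusion Graph Embeddings for miRNA-Disease Association
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a
    heterogeneous network built out of verified associations, miRNA
    functional similarity and disease semantic similarity.  Implements
    Gaussian interaction profile kernel similarity, Wang- and Xuan-style
    disease semantic similarity over MeSH-like disease DAGs, exhaustive
    meta-path instance enumeration, and a graph-embedding model that
    encodes each meta-path instance with a mean encoder and fuses
    instances and meta-path types with two levels of graph attention,
    trained with a Manhattan-distance contrastive loss.  Includes global
    leave-one-out and repeated k-fold cross-validation, per-disease
    candidate ranking, an attention ablation, and a seeded generator of
    block-structured synthetic datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
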
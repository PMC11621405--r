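Package: nichecov
Title: Niche Interactions and Latent-Factor Covariation in Single-Cell
    Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates single-cell-resolution spatial transcriptomics data by
    label transfer from an scRNA-seq reference via soft mutual-nearest-neighbor
    anchors, infers which niche cell types predict each central cell type with
    a regularized multinomial classifier on neighborhood-composition
    enrichment features, and detects covariation of non-negative latent gene
    programs between co-localized cell types by ridge regression. Includes a
    Langevin-dynamics Lennard-Jones tissue simulator that generates spatial
    ground truths with known pairwise cell-type affinities, and a synthetic
    expression generator with planted cross-type factor coupling, so every
    analysis stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    deldir,
    glmnet,
    igraph,
    mclust,
    RANN,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
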
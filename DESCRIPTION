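Package: pl21gpca
Title: Robust Sparse Graph-Regularized PCA for Tumor Sample Clustering and
    Gene Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Dimensionality reduction of gene expression matrices by a
    robust, sparse, graph-regularized principal component analysis: an
    Lp quasi-norm (0 < p < 1) reconstruction loss for robustness to
    outliers, an L2,1-norm penalty on the gene loading matrix for row-wise
    (gene) sparsity, and a graph-Laplacian penalty on the sample embedding
    to preserve the local geometry of a k-nearest-neighbor sample graph.
    The non-convex objective is solved by an augmented-Lagrangian
    alternating-direction scheme with a generalized shrinkage operator.
    Includes a K-means evaluation harness (clustering accuracy via optimal
    label assignment, normalized mutual information), a planted-signal
    simulation generator for benchmarking, and downstream gene ranking
    with Pearson-correlation co-expression network module extraction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
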
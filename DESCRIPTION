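Package: netbc
Title: Network-Aided Bi-Clustering of Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneously clusters the genes and samples of a gene
    expression matrix into a checkerboard of non-overlapping bi-clusters by
    minimizing a gene-weighted sum-squared residue with alternating
    multiplicative updates of nonnegative row and column indicator matrices.
    Per-gene weights blend expression variability with importance propagated
    over a gene interaction network by a PageRank-style recursion, so that
    well-connected, variable genes steer the factorization. Includes
    consensus-based selection of the number of gene and sample clusters via
    the cophenetic correlation coefficient, generators for synthetic
    benchmarks with implanted bi-clusters of five archetypes, and
    clustering-quality metrics (Rand index, pairwise F1, bi-cluster
    relevance and recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    dplyr
Config/testthat/edition: 3
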
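Package: banddepth
Title: Band-Based Similarity Indices and Modified Band Depth for Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact combinatorial computation of the finite-dimensional Modified
    Band Depth (MBD) for any band size, and of per-coordinate band-inclusion
    contingency tables for every pair of observations in a multivariate sample.
    From these tables eight classical binary similarity coefficients (simple
    matching, Jaccard, Simpson, Forbes, Dice, Anderberg, Ochiai, Russell-Rao)
    are aggregated into sample-dependent similarity and dissimilarity matrices
    suitable for classifying and clustering gene expression profiles. Includes
    a k-nearest-neighbour classifier for arbitrary precomputed dissimilarities
    with deterministic tie handling, partitioning-around-medoids and
    complete-linkage evaluation wrappers, clustering error rate and adjusted
    Rand index, supervised (between/within sum of squares) and unsupervised
    (variance) gene filters, Gaussian simulation models and experiment runners
    that benchmark the band-based indices against classical distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
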
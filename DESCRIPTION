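Package: netbounds
Title: Ecological Boundary Analysis of Bipartite Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting discontinuities in bipartite ecological
    interaction networks (such as plant-frugivore networks) across
    large-scale ecological boundaries. Provides Whittaker/Sorensen-family
    network beta-diversity (species turnover, interaction dissimilarity,
    and rewiring of shared species), weighted network-structure metrics
    (weighted connectance, weighted nestedness wNODF, interaction
    evenness, mean paired difference index, and Barber modularity
    optimised by weighted label propagation), construction of predictor
    distance matrices (boundary membership, environmental PCA distances,
    Haversine spatial distance, absolute differences, Gower mixed-type
    distances and principal coordinates), a GAM-based multiple regression
    on distance matrices with permutation inference, deviance
    partitioning with fixed smoothing, jackknife sensitivity analysis by
    study, and a seeded synthetic-data generator for end-to-end testing
    of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
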
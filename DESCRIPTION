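Package: plsDeltaNet
Title: Differential Multi-Omics Association Networks via Partial Least
    Squares and Delta Eigenvector Centrality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative genomic-metabolomic network analysis for stratified
    cohorts. Screens single nucleotide variants for association with a binary
    stratum by genotypic chi-square tests, prunes linked variants, preprocesses
    metabolite abundances (missingness filtering, K-nearest-neighbour
    imputation, Yeo-Johnson transformation, standardization), builds
    stratum-specific multi-block association networks from partial least
    squares component similarities, detects weighted communities, and ranks
    features that differentiate the strata by the change in eigenvector
    centrality (delta centrality) between networks. Includes a synthetic
    cohort generator with planted group-specific cross-omics effects and a
    ground-truth registry for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
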
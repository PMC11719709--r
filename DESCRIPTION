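Package: devoalign
Title: Cross-Species Developmental Trajectory Alignment by Optimal Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative single-cell developmental analysis for two species
    sampled over embryogenesis: QC filtering and normalization of sparse UMI
    count matrices, linear embedding and graph clustering, unbalanced entropic
    optimal transport between consecutive time points with iterative growth-rate
    learning, fate probabilities and barycentric (triangle) commitment views,
    transport-derived lineage trees, ortholog-restricted joint embedding with
    earth-mover-distance alignment of developmental time courses, and cell-level
    regulator-target co-expression with classification of regulatory-interaction
    evolution (conserved, temporally or spatially shifted, lost, novel). Includes
    a two-species embryo simulator with branching lineages, specification delays,
    differential proliferation, and injected co-expression as ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    knitr,
    rmarkdown,
    ggplot2
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
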
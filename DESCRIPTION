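Package: spatchrom
Title: Spatial Coherence Analysis of Chromatin State Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing spatially resolved histone-modification
    profiles (spatial CUT&Tag and related spot-grid assays). Builds tile and
    gene-activity matrices from fragment files, detects spatially coherent
    genes on a k-nearest-neighbour spot network with an edge-based Fisher
    statistic, groups them into co-localization modules with metagenes, maps
    modules to spot clusters by parametric gene-set enrichment (PAGE), calls
    nucleosome- and domain-level chromatin states from binarized pseudobulk
    tracks to identify broad promoter domains, rigidly aligns serial tissue
    slices by iterative closest point registration to transfer a second
    mark's scores, and traces domain-width transitions across tissue
    boundaries along a diffusion-map based spatial pseudo-distance. Includes
    a synthetic-data generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Matrix,
    igraph,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
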
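Package: dawn
Title: Screen-and-Clean Detection of Risk Genes with Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the DAWN (Detecting Association With Networks)
    screen-and-clean algorithm for nominating disease risk genes by combining
    gene-level rare-variant association scores with a gene co-expression
    network. A hidden Markov random field with an Ising prior over a
    thresholded co-expression node graph screens for clusters of association
    signal (nASD genes); a stratified two-component Gaussian-mixture local
    false discovery rate then cleans the screened list (rASD genes), taking
    the minimum FDR over several modular representations of the network.
    Includes WGCNA-style module detection (soft-power adjacency, topological
    overlap, dynamic branch cutting, eigengene merging), multi-gene node
    collapsing, network scores, connectivity and dilution permutation
    experiments, robustness (validation-score) cross-validation, enrichment
    statistics, a de novo mutation occupancy extrapolation model, and a
    synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
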
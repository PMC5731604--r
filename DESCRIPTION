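Package: modsep
Title: Disease Module Separation and Missing Common-Gene Prediction on
    Protein Interactomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-medicine tools for quantifying the topological
    separation of two disease modules on a protein-protein interactome and
    for predicting missing common (shared) genes of a comorbid disease
    pair.  Module separation compares the mean nearest-neighbour shortest
    path distance between two disease gene sets with the within-set
    distances; candidate shared genes are ranked by how much marking them
    as common to both diseases reduces that separation.  Includes the
    all-pair-average separation variant, exhaustive k-subset and
    sequential multi-gene recovery, a seeded cross-validation scheme with
    ROC scoring, Youden-style threshold selection, precision/recall and a
    randomized-common-gene baseline, stratified reporting by comorbidity
    relative risk and overlap size, a synthetic benchmark generator with
    planted disease modules, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
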
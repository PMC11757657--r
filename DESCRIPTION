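Package: pannetips
Title: Infiltration Pattern Scoring of Pancreatic Neuroendocrine Tumors from
    Cell-Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step pipeline for grading the infiltration pattern of
    pancreatic neuroendocrine tumors (PanNETs) from whole-slide image tilings.
    Patches are classified into tumor, non-neoplastic parenchyma and stroma to
    build a slide-level prediction map; representative patches are selected
    along the tumor-parenchyma interface with breadth-first hop distances;
    each patch is modelled as a cell-graph over nucleus centroids with
    morphology features; and a message-passing graph neural network trained
    under a distance-weighted cross-entropy ("infiltration loss") classifies
    patches, whose predictions are voted into a case-level infiltration
    pattern score (IPS1-IPS3). Includes a synthetic-cohort generator that
    emulates the statistical structure the pipeline assumes, a stratified
    cross-validation harness, and classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    Matrix,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
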
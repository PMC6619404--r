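Package: energyscape
Title: Energy-Landscape Analysis of Binarized Multichannel Brain Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits pairwise maximum-entropy (Ising) models to binarized
    region-of-interest time series by exact-enumeration moment matching,
    derives the discrete energy landscape (local minima, disconnectivity
    tree, attraction basins), classifies per-volume brain states into
    synchronized and basin categories, and computes per-individual
    transition statistics including the efficiency score that relates
    ease of transitions between the fully synchronized states to
    peripheral basin-to-basin movement. Includes an exact Boltzmann
    sampler and a two-group synthetic cohort generator with behavioral
    scores for end-to-end validation, a Metropolis-Hastings simulator of
    landscape-constrained dynamics, and individual-level statistics
    (Tukey outlier exclusion, Fisher-z averaged functional connectivity,
    efficiency-behavior correlation).
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
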
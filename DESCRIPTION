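Package: lateralize
Title: Behavioral Lateralization Analysis for Free Movement Pattern
    Y-Maze, Avoidance Conditioning and Novel Tank Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies spontaneous motor lateralization of fish from
    automated Y-maze arm-entry logs: tetragram search-strategy profiles
    (16 overlapping four-choice words), alternation and repetition
    scores, left/right bias percentages with per-bin consistency (mean
    and coefficient of variation across 10-min bins), and a strict
    greater-than-threshold three-way laterality classification.  Also
    scores Pavlovian avoidance conditioning (baseline versus probe CS+
    preference from tracked trajectories) and novel-tank anxiety
    endpoints (thirds occupancy, distance, immobility, thigmotaxis), and
    ships first-order Markov turn-sequence and reflected-random-walk
    trajectory simulators with closed-form oracles so every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
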
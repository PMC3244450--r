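Package: conflictadapt
Title: Conflict-Monitoring Simulation and Distractor-Interference Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying adaptive executive control in pop-out
    distractor experiments. Simulates the conflict-monitoring control
    loop as a seeded difference equation, sweeps its parameters (control
    adaptation, base-level control, conflict gain) over a Monte Carlo
    grid, and evaluates correlation-based criteria for when two
    experimental factors have dissociable effects on control and control
    adaptation. A companion pipeline computes distractor interference and
    its conflict-driven (congruency-sequence) modulation from trial-level
    reaction times with standard exclusion rules, mixed-design ANOVA
    summaries, and subject-level correlations, and a synthetic-cohort
    generator emulates the factorial valence-by-arousal design so every
    stage is testable without access to raw data.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
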
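Package: tempovar
Title: Temporal Variation of Stochastically Growing Microbial Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: First-passage-time statistics for exponentially growing microbial
    populations. Provides exact abundance and threshold-crossing distributions
    for the simple birth (Yule) process, temporal-variation statistics for
    zero-truncated Poisson inocula growing deterministically, event-driven
    simulators for age-structured (Bellman-Harris) growth, a noise-based
    growth-rate estimator with bootstrap uncertainty, a plate-reader OD600
    growth-curve analysis pipeline (background removal, quality control,
    log-window growth rates, temporal standard deviation versus threshold,
    lag-phase diagnostics), synthetic plate and spot-count generators, and a
    renewal-equation analysis of division-time desynchronization.
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
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
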
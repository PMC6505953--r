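Package: ctfiem
Title: Inverted Encoding Models and Channel-Tuning Functions for Oscillatory EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs spatially selective channel-tuning functions (CTFs)
    from the multivariate topography of band-limited EEG power using an
    inverted encoding model (IEM), and quantifies their spatial selectivity
    as CTF slope. Provides band-pass filtering and Hilbert-based instantaneous
    power estimation, trial partitioning and cross-validation in
    condition-neutral, within-condition, and cross-training regimes,
    cluster-based permutation inference over time and time-frequency,
    a simulated-switching null for multi-item working-memory storage,
    von Mises mixture modeling of continuous-report behavior, and a fully
    synthetic data generator plus simulation-study harness for validating
    the IEM's behavior under added representations, noise, and amplitude
    reduction.
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
    signal,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
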
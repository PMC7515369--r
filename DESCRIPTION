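Package: entrobench
Title: Entropy Estimators and Synthetic Benchmark Signals for Biomedical
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Five entropy estimators for nonlinear time-series analysis
    (permutation, modified permutation, sample, quadratic sample, and fuzzy
    entropy), a suite of ten synthetic benchmark signals that characterise
    their responses to frequency, harmonics, noise power, noise bandwidth,
    and transitions between stochastic, periodic, and chaotic regimes, a
    sliding-window entropy-curve engine, and an EEG study pipeline
    (band-pass preprocessing, nonparametric group comparisons, and k-nearest
    neighbour classification over entropy features).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
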
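Package: ssastream
Title: Streaming Ensemble Stochastic Simulation with Online Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie direct method) of reaction
    systems written in flat chemical notation, with mass-action or arbitrary
    state- and time-dependent rate functions, run as ensembles of independent
    trajectories streamed through an online analysis pipeline. Trajectories are
    advanced in simulation-time quanta under slowest-first scheduling, aligned
    into per-time ensemble cuts, and analysed on the fly: summary statistics
    (mean, standard deviation, quantiles), sliding-window trajectory clustering
    (K-means and quality-threshold) on Savitzky-Golay filtered values and
    forecasts, and peak/frequency detection for oscillatory systems. Includes
    built-in Schlogl, bacteriophage lambda lysis/lysogeny, and Neurospora
    circadian clock models, and an analytic pipeline/farm service-time model
    for sizing worker pools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    signal,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
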
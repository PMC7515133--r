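Package: nprd
Title: Neural and Analytic Estimation of Predictive Rate-Distortion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the predictive rate-distortion curve of a
    discrete-valued stationary stochastic process: the trade-off between the
    information a summary of the past retains (rate) and how well the future
    can be predicted from that summary (predictiveness). Provides exact
    curves for analytically known unifilar hidden Markov models (epsilon-
    machines) via an information-bottleneck Blahut-Arimoto iteration, the
    Optimal Causal Filtering baseline built on smoothed block counts, and a
    neural variational estimator (NPRD) that compresses past observations
    with a recurrent Gaussian encoder, models the code marginal with an
    autoregressive flow, and reports held-out variational bounds on rate and
    prediction loss. Includes simulators for benchmark processes (Even
    Process, Random Insertion Process, Copy3), Pareto-frontier aggregation
    of runs, and a parametric ansatz fit based on the incomplete gamma
    function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
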
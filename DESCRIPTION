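Package: wmrnn
Title: Recurrent Agents and Strategy Analyses for Working-Memory Match Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains gated recurrent (LSTM) agents with advantage actor-critic
    reinforcement learning on delayed match-to-sample working-memory tasks
    (Same-Different, Match-First, Match-Any) and provides the behavioral and
    neural state-space analyses used to characterize their learning
    progression: serial position curves with linear-fit slope and residual,
    lead-cue-stratified match-error profiles, PCA of hidden-state activity,
    cue-sorting directions and their angles, intercluster centroid distances,
    and distance-versus-error correlations. Includes a synthetic task
    generator covering scalar (similarity-based) and one-hot cue encodings
    and an optional recency-based reward-shaping scheme, plus orchestration
    for network-size by training-experience grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
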
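Package: noisybandit
Title: Noisy Kalman-Filter Learning and Choice Variability in Restless Bandits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying human learning and choice variability under
    expected and unexpected uncertainty in a three-condition two-armed bandit
    task. Generates matched reward schedules (reference, high-stochasticity
    and high-volatility conditions), simulates noisy Kalman-filter learning
    agents with Weber-scaled learning noise and softmax exploration, estimates
    choice likelihoods by particle filtering, fits per-subject parameters with
    stochastic-tolerant derivative-free optimisation, performs random-effects
    Bayesian model selection with model and parameter recovery, computes
    marginal and joint reward costs of learning noise and choice temperature
    by simulation, and provides the statistical layer (rank correlations,
    FDR control, median splits, PCA with bootstrap and shuffle nulls) used to
    analyse parameter covariation across synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
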
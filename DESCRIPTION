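Package: jsdesign
Title: Optimal Experiment Design for Bayesian Model Selection via
    Predictive Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate experiments by how well they would discriminate
    between competing mechanistic models of biochemical networks. Competing
    models (linear basis-function regressions or ODE models with Gaussian
    error) are fitted in a Bayesian framework -- analytically for the
    linear-Gaussian case, by population Markov chain Monte Carlo with a
    power-posterior temperature ladder otherwise. Posterior predictive
    distributions are sampled for arbitrary candidate observations
    (observable, time point, stimulus condition, singly or in combination)
    and candidate experiments are scored by a k-nearest-neighbour estimate
    of the Jensen-Shannon divergence between the models' multivariate
    predictive densities. Marginal likelihoods (analytic or by thermodynamic
    integration), Bayes factors, and Monte-Carlo expected Bayes-factor
    updates are provided to validate the divergence-based ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
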
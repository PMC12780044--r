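Package: tpslearn
Title: Transition Path Sampling with Adaptively Learned Committor Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for AI-guided transition path sampling (TPS) of rare
    events: two-way shooting Markov chains over pluggable stochastic
    engines, on-the-fly learning of the committor function from shooting
    outcomes via a feed-forward/residual network trained on the binomial
    shooting likelihood, Cauchy-logit shooting-point selection with
    histogram reweighting, sampler efficiency diagnostics, a beta-binomial
    estimator of committor-model accuracy with bootstrap and
    cross-validation, logit-logit calibration analysis, reactive-flux
    direction and quasi-linear committor analysis, membrane pore
    reaction-coordinate geometry on particle configurations, and a
    censored-exponential estimator of pore lifetimes. Synthetic-data
    generators (toy potentials, overdamped Langevin and discrete-chain
    engines, membrane-like configurations with plantable water pores,
    dispersed shot records, censored lifetimes) make every stage testable
    against exact or brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
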
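Package: shareddm
Title: Simulated Social-Media Incentive Experiments and Hierarchical
    Drift-Diffusion Modelling of Sharing Discernment
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how veracity-coupled social feedback (trust and
    distrust reactions) changes the discernment of information sharing on
    simulated social-media platforms. Provides generators for reaction-study,
    sharing-study, belief-rating and memory-check data; per-participant
    discernment and belief-error statistics with one-sample t and ANOVA
    group tests; a four-parameter Wiener diffusion model (drift rate,
    boundary separation, relative starting point, non-decision time) with a
    dual-series first-passage-time density, closed-form choice probabilities
    and an Euler-Maruyama simulator; hierarchical Bayesian estimation of
    group- and subject-level diffusion parameters by adaptive
    Metropolis-within-Gibbs MCMC; Gelman-Rubin convergence diagnostics,
    highest-density-interval group comparisons, posterior-predictive
    simulation and parameter-recovery reports; and a seeded, config-driven
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
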
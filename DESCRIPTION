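Package: protectRL
Title: Two-Step Decision Task Simulation and Hybrid Reinforcement
    Learning Inference for Protection Acquisition
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a two-step sequential decision task with
    deterministic state transitions, drifting second-stage payoffs and
    per-trial stakes amplification, in four outcome framings (protection,
    reward, direct reward, punishment avoidance).  Fits hybrid
    model-based/model-free reinforcement-learning models to choice data
    with hierarchical Bayesian inference (non-centered parameterization,
    adaptive MCMC), compares parameter-tying schemes by WAIC, and
    provides model-agnostic analyses: stay-probability logistic mixed
    models, corrected reward rate, and metacognitive/predictive bias
    slopes.  Includes a synthetic-cohort generator so the full pipeline
    runs offline, plus parameter- and model-recovery utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
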
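Package: nonmarkov
Title: Simulation and Model Comparison for Non-Markovian Decision Making
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulators for two prototypical non-Markovian learning paradigms
    (switch-state navigation, where a goal transition is gated on having
    visited a designated state first, and image classification with
    gamma-delayed, randomly intermixed feedback), four families of learning
    agents (a population-of-spiking-neurons policy-gradient learner with a
    cascade of three eligibility traces, three sequence/transition Bayesian
    learners with a Monte-Carlo tree MAP planner, a Dirichlet-process learner
    over the feedback-delay distribution, and a one-parameter softmax policy
    gradient baseline), and an evaluation layer that builds learning curves
    and compares models by residual sum of squares and finite-sample
    corrected AIC. Includes a synthetic surrogate-curve generator so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
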
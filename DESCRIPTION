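Package: rewardscape
Title: Reward-Landscape Models of Reinforcement-Based Sensorimotor Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the gradient of a reinforcement landscape
    shapes trial-by-trial sensorimotor learning. Provides piecewise-linear
    reward landscapes over baseline-normalized reach angle, a three-parameter
    success-gated learning model (aim update after rewarded reaches, extra
    exploration variance after unrewarded ones) in one and two dimensions,
    numerical expected-reward curves and the reward-maximizing intended aim,
    exponential learning-curve fits with participant-level bootstrap
    inference, learner classification, Nth-success prediction,
    variability-by-reinforcement-history summaries, simulation-based
    parameter fitting with recovery diagnostics, and configurable
    replication scenarios (gradual target rotation, stochastically shifted
    cursor, rectangular-target random walks, movement-variability sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
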
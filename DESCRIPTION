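Package: imusac
Title: Inertia-Constrained Soft Actor-Critic for Simulated Human Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Trains simulated walking agents with a Soft Actor-Critic whose
    reward is a ten-component vector combining trajectory-optimization terms
    (alive bonus, stepping, velocity tracking, effort) with bio-inspired
    terms penalising deviation of the simulated pelvis orientation from a
    reference IMU (roll/pitch/yaw) gait trace.  Each reward component owns
    its own Q head; the actor optimises the weighted scalarization, so
    components can be added or removed without retraining from scratch.
    Includes overlapping-segment prioritized experience replay with n-step
    targets and invertible value rescaling, a second-stage policy/critic
    distillation conditioned on a local target-velocity field, a
    self-contained synthetic planar walker environment, a synthetic
    reference-IMU generator, and per-axis RMSE evaluation of rollouts
    against the reference trace.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
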
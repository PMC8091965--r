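Package: nmmexo
Title: Neuromuscular-Model Ankle Exoskeleton Controller Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale simulator for a reflex-driven neuromuscular-model
    (NMM) ankle exoskeleton controller: a lumped Hill-type plantarflexor
    muscle-tendon unit (contractile element in series with a nonlinear
    tendon) stimulated by a delayed positive force-feedback reflex, driven
    by ankle kinematics and scaled to an assistive exoskeleton torque.
    Includes a synthetic treadmill-gait generator (ankle angle, surface
    EMG, breath-wise gas exchange), the stride-averaged outcome metrics
    used in gait studies (average torque, net mechanical power, EMG
    envelopes, Brockway metabolic rate), a Gain/Delay condition sweep
    engine with an optional kinematic-admittance human-adaptation plant,
    and the accompanying statistics (repeated-measures ANOVA,
    Bonferroni-corrected pairwise comparisons, least-squares regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
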
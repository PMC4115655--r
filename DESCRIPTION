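Package: hdtheta
Title: Head-Direction Tuning and Theta-Cycle-Skipping Analysis of Single Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-unit analysis of freely moving rodent recordings in open
    arenas: head-direction tuning curves in 5-degree bins with normalization,
    180-degree peak alignment and clockwise/counter-clockwise separation at an
    angular-velocity threshold; Skaggs spatial information, selectivity and
    place-field detection on occupancy-normalized rate maps; spike-train
    autocorrelograms fitted with a bounded damped two-cosine model yielding
    the jump factor, frequency ratio and theta-cycle-skipping index; a
    distributive-hypothesis directional prediction to rule out spatial
    confounds; and an inhomogeneous-Poisson session simulator (foraging
    trajectories plus von Mises directional, Gaussian spatial and dual
    theta/half-theta oscillatory intensities) providing ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
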
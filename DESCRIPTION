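Package: beamcascade
Title: LCMV Beamformer Source Localization Under Forward-Model Simplification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how forward (head) model
    simplification affects EEG/MEG beamformer source localization. Provides
    analytic multi-shell spherical EEG and spherical-conductor MEG leadfields
    with a controlled model-perturbation cascade, an interictal-spike
    measurement simulator, scalar linearly constrained minimum variance (LCMV)
    beamformers under unit-gain, unit-array-gain and unit-noise-gain
    constraints with data-driven dipole orientation, variance and excess
    kurtosis (g2) localization maps, Tukey-style localization-error summaries,
    and a config-driven experiment driver that replays the model-mismatch
    study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
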
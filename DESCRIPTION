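Package: socens
Title: Social Behavior-Tuned Neural Ensembles from Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of head-mounted two-photon calcium imaging
    recorded during three-stage social exploration assays (habituation,
    sociability, social novelty). Extracts somatic fluorescence with annular
    ring subtraction (ARS) and converts it to dF/F, aligns 30 Hz behavior
    trajectories to the imaging clock, detects direct-exploration epochs by
    distance thresholding, classifies neurons into socially activated /
    inactivated ensembles with a permutation-null similarity test, detects
    event-associated and social-cue-preferred neurons, summarizes epoch
    activation kinetics (activation probability, rise time, amplitude), and
    characterizes signed functional networks with weighted clustering
    coefficients. Includes a synthetic-session generator with planted ground
    truth (behavior epochs, GCaMP6s-like transients, rendered videos) so the
    whole chain can be validated against known labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5,
    yaml
Config/testthat/edition: 3
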
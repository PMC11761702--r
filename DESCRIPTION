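Package: reachmetrics
Title: Trajectory Stereotypy, Motor-Evoked Potentials and Learning-Curve
    Statistics for Skilled-Reaching Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for rodent single-pellet reaching
    experiments performed under concurrent transcranial direct current
    stimulation (tDCS). Reads markerless pose-tracking tables, scores
    movement stereotypy by normalized template matching against a
    per-session grab template, detects individual grab events, quantifies
    motor-evoked potentials (rectified window means, recruitment curves,
    motor-threshold estimation, contra/ipsilateral log contrasts),
    estimates the intracranial electric field and its current gain from a
    four-contact lattice, calibrates stimulation current for a target
    field, and fits the longitudinal mixed-effects models (success,
    success rate, stereotypy and MEP amplitude against log-day, group and
    their interaction). Includes synthetic-data generators with known
    ground truth for every input kind, so every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
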
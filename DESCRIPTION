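Package: opirasch
Title: Objective Performance Indicators and Rasch Calibration for Gated
    Surgical Skill Rubrics
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes objective performance indicators (speed peaks, path
    lengths, idle time, energy proportion, clutch count) from robotic
    instrument kinematic and console event streams, scores a gated twelve-item
    dichotomous rubric against expert-derived two-standard-deviation norms,
    and calibrates the resulting response matrix with a dichotomous Rasch
    model (marginal maximum likelihood, EAP and weighted-likelihood person
    estimation, mean-square item fit, Wright map, construct-alignment and
    subgroup fairness checks).  Includes a seeded synthetic-cohort generator
    for trajectories, console events, and Rasch response matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
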
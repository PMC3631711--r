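Package: audioreach
Title: Kinematic Analysis of Hand Pointing to Virtual Auditory Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing goal-directed hand pointing movements toward
    spatialised auditory targets recorded with optical motion capture.
    Implements Gaussian low-pass filtering of endpoint trajectories,
    tangential velocity/acceleration/jerk norms, two-stage movement
    segmentation by displacement and relative velocity thresholds,
    acceleration-peak (submovement) counting around the peak-velocity point,
    head heading (yaw) extraction from rigid-body quaternions with range of
    motion and peak-velocity timing measures, azimuthal pointing-error
    computation with an auditory hand-avatar shift transform, a calibrated
    synthetic session generator built on minimum-jerk primitives for
    end-to-end testing, and a repeated-measures analysis pipeline with
    subject exclusion rules, condition-by-target aggregation, within-subject
    ANOVA and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    readr,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
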
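Package: restMVPA
Title: Multivoxel Decoding of Task-Pattern Reactivation in Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect the re-emergence of task-related multivoxel
    activity patterns during awake rest. Implements temporal preprocessing of
    region-of-interest BOLD time series (volume discarding, discrete-cosine
    high-pass filtering, per-voxel z-normalisation), spatiotemporal feature
    extraction over four-volume windows with a hemodynamic label shift, a
    linear support vector machine decoder with leave-one-session-out
    cross-validation, nearest-template classification by Euclidean distance,
    sliding-window scoring of resting-state runs into a task-labelled
    fraction, and cohort-level mixed-design ANOVA, post hoc t-tests and
    reactivation-behaviour correlation. A synthetic-data module generates
    multi-session, multi-subject block-design BOLD datasets with known ground
    truth (planted condition patterns, resting-state reactivation events and
    coupled behavioural improvement) and writes them as NIfTI images with
    BIDS-style event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
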
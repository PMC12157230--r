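Package: gaitFatigue
Title: Multimodal Physical-Fatigue Detection from Wearable sEMG and IMU Gait Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting physical fatigue from natural
    over-ground walking recorded with wearable surface electromyography (sEMG)
    and inertial measurement units (IMUs). Provides multi-rate signal
    conditioning (outlier masking, gap interpolation, zero-phase Butterworth
    band-pass filtering, EMG envelope extraction, linear and angular jerk
    derivation, band-limited resampling to a common frame rate), sliding-window
    segmentation with per-segment z-score normalisation, a registry of sensor
    and signal combinations, a from-scratch CNN-LSTM self-attention binary
    classifier with seeded deterministic training, subject-independent
    (leave-one-subject-out) and subject-dependent (9-fold) cross-validation
    with confusion-matrix metrics and attention-map reporting, and a synthetic
    gait-cohort simulator with controllable fatigue effect sizes for fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'combinations.R'
    'nn.R'
    'model.R'
    'evaluation.R'
    'gaitFatigue-package.R'
    'segmentation.R'
    'preprocess.R'
    'recordings-io.R'
    'synthetic.R'
    'pipeline.R'
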
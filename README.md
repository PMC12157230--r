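# gaitFatigue

Detecting **physical fatigue from natural walking**, using the signals a
wearable lower-limb sensor set actually produces: surface EMG (1259 Hz) and
3-axis accelerometer + gyroscope (148 Hz) at six sites — bilateral tibialis
anterior (TA), gastrocnemius lateralis (GL) and rectus femoris (RF). The
package is for researchers and engineers building gait-based fatigue
monitors who need a complete, deterministic, testable pipeline rather than a
loose collection of scripts.

## What it does

* **Conditioning** per channel: ±3 SD outlier masking → linear gap
  interpolation → zero-phase 4th-order Butterworth band-pass (gyro
  0.25–30 Hz, accel 1–20 Hz, EMG 20–500 Hz at native rate) → derived
  channels → band-limited resampling onto a common 148 Hz grid.
  IMU channels become **linear jerk** and **angular jerk**,
  `j(t) = (x(t+dt) − x(t))/dt`, smoothed with a 100 ms moving average; EMG
  becomes the classic rectified + 100 ms moving-average **envelope**.
* **Segmentation**: 3 s windows (444 frames) with 50 % overlap, nine per
  recording, z-scored per segment and per channel; an *n*-subject cohort
  yields *n* × 2 × 9 exactly balanced segments (35 subjects → 630 × 444).
* **Sensor/signal combinations**: a 14-row registry from single-channel EMG
  (1 feature) to the comprehensive bilateral set (20 features);
  `selectChannels()` slices the normalised dataset.
* **Classifier**: a CNN-LSTM self-attention network written from scratch in
  R — conv(64)+pool → conv(128)+pool → LSTM(64, sequence output) →
  single-head scaled dot-product self-attention `softmax(S Sᵀ/√H)` → global
  average pooling → dense → 2-unit softmax — trained with Adam,
  stratified 80:20 validation split, early stopping and LR reduction. The
  backward pass (including BPTT and attention) is verified against finite
  differences in the test suite. Same config + seed ⇒ bit-identical model.
* **Evaluation**: subject-independent LOSOCV and subject-dependent 9-fold
  (one window index per subject-state per fold), pooled confusion counts
  with accuracy / per-class precision, recall, F1 (fatigued = positive),
  per-subject accuracy tables, learning curves and attention heatmaps.
* **Synthetic cohorts**: a seeded generator of six-site recordings with
  subject-specific latent gait parameters and controllable fatigue effects
  (heel-strike transient gain, EMG burst gain, left-side asymmetry, cadence
  slow-down), used to test the pipeline end to end.

## Worked example

Simulate a 4-subject cohort with the default (moderate) fatigue effects,
check the effects the generator realized, and run a subject-independent
evaluation of combination 13 (GL EMG + TA linear & angular jerk + RF linear
jerk, 10 features):

```r
library(gaitFatigue)

params <- simulationParams(nSubjects = 4, seed = 42)
effectReport(params)
#>   subject jerkRatio emgRatio asymmetryNonFatigued asymmetryFatigued
#> 1     S01  1.258883 1.329444           0.07732724        0.21420923
#> 2     S02  1.262867 1.309219          -0.21649973       -0.04129991
#> 3     S03  1.211202 1.351781           0.12571125        0.33246139
#> 4     S04  1.253922 1.377197           0.09090375        0.25814941

segs <- simulateSegmentSet(params)
segs
#> SegmentSet: 72 segments x 444 frames x 42 channels
#>   subjects: 4; labels: 36 non-fatigued / 36 fatigued

report <- runCV(segs, spec = 13, protocol = "losocv",
                cfg = smallModelConfig(), seed = 42)
report
#> EvalReport [losocv, combination 13]: 4 folds, 72 test segments
#>   pooled accuracy 0.7222; recall(F) 0.8056; recall(NF) 0.6389
report@perSubject
#>   subject nSegments  accuracy
#> 1     S01        18 1.0000000
#> 2     S02        18 0.7222222
#> 3     S03        18 0.6111111
#> 4     S04        18 0.5555556
```

Reading the numbers: the jerk RMS rises ~1.21–1.26× and the EMG envelope
~1.31–1.38× from the non-fatigued to the fatigued recording of each subject
(the EMG ratio sits above the configured 1.25 because the left-side
asymmetry gain also raises the left GL burst), and the signed left-right
asymmetry index shifts upward under fatigue for every subject. With these
moderate effects and only 3 training subjects per fold, held-out-subject
accuracy lands at 0.72 — between chance (a null cohort with all gains at
1.0 scores ≈ 0.5) and the ≥ 0.9 reached on strong-effect cohorts with 8
subjects. Per-subject accuracy varies widely (0.56–1.00), the expected
signature of subject-independent evaluation.

`renderReports(report, "outdir")` writes the confusion matrix, per-subject
table, learning curves and attention heatmaps as CSV/JSON. A thin CLI over
the same functions lives at `inst/scripts/gaitfatigue.R`
(`simulate` / `eval` / `sweep` subcommands).

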
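---
title: "Methods: multimodal fatigue detection from wearable gait signals"
author: "gaitFatigue authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal fatigue detection from wearable gait signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Physical fatigue changes how people walk and how their muscles fire:
lower-limb jerk (the time derivative of acceleration) rises, surface EMG
amplitude grows, left-right muscle activity becomes more asymmetric, and
cadence drops. `gaitFatigue` implements a complete pipeline that turns
multi-rate wearable recordings — six sensor sites on the lower limbs
(bilateral tibialis anterior, gastrocnemius lateralis, rectus femoris), each
with a 148 Hz 3-axis accelerometer + gyroscope and a 1259 Hz sEMG channel —
into a binary *non-fatigued vs. fatigued* classification of natural
over-ground walking, evaluated both subject-independently and
subject-dependently.

Because raw human cohorts of this kind are not freely available, the package
ships a first-class synthetic cohort generator with controllable fatigue
effect sizes, so that every stage of the pipeline is exercised and tested
end to end without external data.

## Signal conditioning

Each channel passes through a fixed chain, in this order:

1. **Outlier masking.** A single pass computes the channel's mean and SD over
   unmasked samples; samples beyond ±3 SD join the missing mask. One pass,
   not iterated: re-running the rule on its own output would keep shaving the
   tails of a clean distribution.
2. **Gap interpolation.** Masked interior samples are filled linearly between
   their nearest unmasked neighbours; leading/trailing gaps copy the nearest
   value. Idempotent.
3. **Zero-phase band-pass.** 4th-order Butterworth applied forward-backward
   (`signal::filtfilt`): gyroscope 0.25–30 Hz, accelerometer 1–20 Hz, EMG
   20–500 Hz. Zero-phase filtering matters here because jerk is a derivative:
   a modality-dependent group delay would skew the timing of jerk transients
   relative to the EMG envelope. The EMG band's 500 Hz edge sits above the
   148 Hz common-grid Nyquist, so EMG filtering happens at the native
   1259 Hz *before* envelope extraction and resampling.
4. **Derived channels.** IMU: linear jerk and angular jerk as forward
   differences `(x(t+dt) − x(t))/dt`, then a 100 ms moving average. The jerk
   is differentiated first and smoothed second — smoothing the raw IMU signal
   and then differencing would re-amplify exactly the noise the smoothing
   removed. The "angular jerk" channel is, as conventionally derived in this
   setting, the first derivative of angular velocity (rad/s²);
   `angularJerk(order = 2)` exposes the literal second derivative for users
   who want the rate of change of angular *acceleration* instead.
   EMG: full-wave rectification, then the same 100 ms moving average — the
   classic linear-envelope estimator.
5. **Resampling to 148 Hz.** `resampleSignal()` low-pass filters at 90 % of
   the target Nyquist (zero-phase Butterworth) and evaluates the result on
   the target time grid. We verified that the general-purpose
   `signal::resample` polyphase routine overshoots a 5 Hz test sinusoid by
   ~7 % at the 1259→148 conversion, which violates the 1 % in-band
   amplitude-preservation contract this package tests for; the
   filter-then-interpolate design meets it comfortably because everything
   surviving the anti-alias filter is far below the input rate.
6. **Truncation** of all channels to the common minimum frame count.

Moving-average windows are `round(0.1·fs)` samples, forced odd (+1) so the
window has an unambiguous centre; edges shrink the window rather than pad.

## Windowing and normalisation

Recordings are cut into 3 s windows (444 frames at 148 Hz) with 50 % overlap
(222-frame hop); exactly 9 windows are kept per recording, counted from the
start. Each window is z-scored **per segment, per channel**; a zero-variance
channel becomes zeros. The per-segment scope is a deliberate choice: scaling
never uses statistics from other subjects or other time ranges, which keeps
leave-one-subject-out evaluation honest (no normalisation leakage), and it
removes inter-subject amplitude offsets exactly where they would otherwise
dominate. The consequence — also a modelling statement — is that *absolute*
amplitude differences between states are invisible to the classifier; what
remains are shape, timing and ratio cues (burst-to-background contrast,
transient sharpness, cadence).

A cohort of `n` subjects yields `n × 2 × 9` segments with exact class
balance; 35 subjects give the canonical 630 × 444-frame dataset.

## Sensor/signal combinations

`listCombinations()` tabulates the 14 evaluated configurations, from single
EMG channels through jerk-only setups to the comprehensive 20-feature
bilateral set. A combination expands to EMG envelope (1 channel per site)
plus jerk blocks (3 axes per site and jerk type); hybrid rows list EMG
first. Channel selection happens after normalisation, so a combination's
values are literally a slice of the full set (per-segment z-scores are
slice-invariant) — the sweep over combinations therefore reuses one
preprocessed cohort.

## The classifier

The model is a compact CNN-LSTM self-attention network, written from
scratch in R (no deep-learning framework is involved), with the backward
pass verified against finite differences in the test suite:

* two 1-D convolution blocks (64 then 128 filters by default, kernels 5 and
  3, ReLU, same padding), each followed by non-overlapping max-pooling —
  pooling after *each* convolution, the usual reading of "convolution
  combined with max-pooling";
* a single 64-unit LSTM returning its full state sequence;
* single-head scaled dot-product self-attention over the LSTM states
  (queries = keys = values = states, weights `softmax(S Sᵀ/√H)` row-wise) —
  the lightweight alternative to multi-head Transformer attention;
* global average pooling over time, one ReLU dense layer, and a 2-unit
  softmax head trained with cross-entropy.

Training uses Adam (learning rate 1e-3, batch 16), an internal stratified
80:20 train/validation split, early stopping on validation loss
(patience 10) with best-weights restoration, and learning-rate halving
after 5 stale epochs. Every unstated hyperparameter is a documented
`modelConfig()` default rather than a hidden constant. All randomness —
initialisation (Glorot uniform, forget-gate bias 1), the split, shuffling,
dropout (0.3 after the second pooling block) — derives from `cfg$seed`, so
identical configuration and seed reproduce identical parameters, history
and predictions. Ties in the argmax resolve to class 0 (non-fatigued).

`smallModelConfig()` (8/16 filters, 16 LSTM units, pool width 4, ≤30
epochs) is the configuration used for the package's own synthetic
experiments: an 8-subject synthetic cohort is a far lower-dimensional
discrimination task than a real 35-subject cohort, and the compact model
trains in seconds per fold on one CPU. The vignette-scale experiments below
use 2–8 subjects; the package's acceptance checks use 8 subjects × 3 seeds.

## Evaluation protocols

* **LOSOCV** (subject-independent): one fold per subject; the fold tests on
  all 18 of that subject's segments and trains on everyone else.
* **9-fold subject-dependent:** fold *j* tests window index *j* of every
  subject in both states (2 × n subjects per fold, exactly label-balanced),
  training on the other eight indices. Note an inherent property of this
  design: 50 %-overlapping windows share frames between train and test
  folds. The package reproduces this faithfully rather than "fixing" it,
  because it is part of why subject-dependent accuracy runs above LOSOCV in
  this kind of study; the vignette flags it so nobody mistakes kfold9
  numbers for generalisation estimates.

Metrics come from pooled confusion counts (fatigued = positive class), with
per-class precision/recall/F1 obtained by swapping the positive class;
macro-averaged per-fold accuracy is reported alongside (identical for equal
fold sizes). Degenerate ratios (0/0) return 0 with a flag. `renderReports()`
writes the confusion matrix, per-subject accuracy table (radial-chart data),
per-fold learning curves and attention heatmap matrices as CSV/JSON.

## The synthetic cohort

`simulationParams()` fixes the study conditions. Each subject has latent
gait parameters — cadence ~0.9 strides/s with 5 % log-normal jitter, a
random stride phase, per-site log-normal amplitude factors (SD 0.15), a
second-harmonic mix — shared between their two recordings. Signals are
stride-locked sinusoids plus damped heel-strike transients (Gaussian
envelope, ~14 Hz oscillation, strongest at the shank) for the IMU, and
stride-phase-gated bursts of 20–450 Hz band-limited noise for the EMG,
synthesised at the native 1259 Hz so the resampling path is genuinely
exercised. Recording length is 16 s — comfortably above the 15 s that nine
3 s / 50 % windows require.

Fatigue applies four multiplicative effects: `jerkGain` (default 1.3) on
the heel-strike transients, `emgGain` (1.25) on the burst envelope,
`asymmetryGain` (1.2) once more on the left side, and `cadenceFactor`
(0.92) on stride rate. The defaults are the package's fixed choice of a
plausible moderate effect; the human literature reports the *directions*
(jerk up, EMG amplitude up, asymmetry up, cadence down) but no portable
effect sizes. Critically, the gains act on the transient/burst components,
not on whole channels — a whole-channel gain would be erased by per-segment
z-scoring, whereas real fatigue changes the *shape* of the signal. The
additive noise floors are deliberately not scaled, so the discriminative
cue is burst-to-background contrast, which survives normalisation.

`effectReport()` verifies what the generator actually realizes: with the
jerk gain isolated at 1.3 and low noise, the raw-signal jerk RMS ratio lands
in [1.25, 1.35]; the EMG envelope ratio tracks `emgGain` (slightly above it
when `asymmetryGain > 1`, which also raises the left GL burst — visible in
the worked example in the README); the signed asymmetry index
`(L − R)/mean` rises under fatigue. The index is signed because the gain is
applied to a known side; an unsigned index could *fall* for a
right-dominant subject.

What the generator does **not** emulate: musculoskeletal waveform realism,
gait-event variability beyond cadence jitter, electrode-contact artifacts,
orientation drift, or any coupling between effects and RPE. Passing the
package's acceptance checks therefore demonstrates that the pipeline
recovers known, well-posed effects through the full preprocessing +
learning stack — not that the classifier reaches any particular accuracy on
real human data.

## Numerical choices and degenerate inputs

* Forward (not central) differences for jerk, matching the defining
  difference quotient; the final frame is replicated to preserve length.
* Even moving-average windows are rounded up to odd for a symmetric centre.
* Band-pass design is validated analytically (the transfer function is
  exactly zero at DC) and behaviourally (≥20 dB attenuation at DC and at
  twice the high band edge in the signal's steady-state region, mid-band
  within 5 %).
* Zero-variance channels z-score to zeros; all-zero segments produce valid
  softmax outputs (no NaN).
* IMU/EMG stream durations must agree within 0.05 s — a duration-based
  tolerance rather than an exact sample-count ratio, since independently
  clocked devices rarely agree to one sample over a full recording.
* All seeds are kept below 2³¹; per-subject and per-recording RNG streams
  are derived from the master seed, so a subject's data are independent of
  cohort size.

## Known limitations

* The classifier is an R reference implementation: fine for the package's
  cohort sizes (seconds per fold with `smallModelConfig()`), but a
  35-subject LOSOCV sweep at full 64/128/64 capacity is an overnight job,
  not an interactive one.
* Heel-strike *detection* is out of scope; windows are fixed-time, not
  gait-cycle-anchored.
* The kfold9 protocol's window-overlap leakage is reproduced by design (see
  above).
* Sensor-fusion orientation estimation (Kalman/Madgwick), gravity removal
  and axis auto-alignment are out of scope; units are fixed conventions
  (m/s², rad/s, mV) and never converted.
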
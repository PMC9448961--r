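---
title: "Estimating the pulmonary artery pressure waveform from noninvasive signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the pulmonary artery pressure waveform from noninvasive signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papwave)
```

## The problem

Pulmonary artery pressure (PAP) is measured invasively, by a catheter placed
in the pulmonary artery. `papwave` implements a signal-processing and
machine-learning pipeline that estimates the continuous PAP *waveform* — not
just a summary pressure — from bedside channels, primarily the three that
can be obtained noninvasively: the ECG (lead II), the photoplethysmogram
(PPG) and the respiration waveform (RESP). Arterial blood pressure (ABP) and
central venous pressure (CVP) can be added as a five-signal input variant,
which lets a user quantify how much the invasive channels contribute.

The pipeline has five phases: preprocessing (band-pass filtering),
segmentation (sliding windows), feature extraction (a wavelet scattering
transform), regression (a model registry of eleven families, including a
1-D residual convolutional network), and evaluation (waveform metrics plus
per-beat systolic/diastolic agreement, with bootstrap confidence
intervals). Per-beat systolic (SBP) and diastolic (DBP) pressures are
extracted from the estimated waveform under an ECG-derived beat-count
constraint.

All development and testing run against a synthetic coupled-hemodynamics
simulator rather than patient recordings, so every stage is verifiable
against known ground truth without any data download.

## The synthetic simulator

`simulate_record()` generates the six channels on a common 125 Hz grid from
one latent state:

* a beat process — per-beat instantaneous heart rate drawn i.i.d.
  Gaussian (mean `heart_rate_bpm`, SD `hr_sd_bpm`, truncated at ±3 SD),
  the simplest model that supports testing heart-rate variability effects;
* a respiratory phase — a sinusoid at `resp_rate_bpm`.

Each pressure channel (PAP, ABP, CVP) is a beat-synchronous pulse train: a
raised-cosine upstroke over the first 30% of the cycle followed by an
exponential decay (rate 4) back toward the diastolic level. Every complete
beat is rescaled *on its own sample grid* so its maximum and minimum equal
the programmed systolic/diastolic values exactly; the ground truth is then
recomputed from the generated noiseless signal per beat, so with
`noise_sd = 0` the recorded per-beat extrema reproduce the ground truth at
machine precision — this is what makes the exact-recovery tests of the beat
extractor meaningful. Respiration multiplies the pressures by
`1 + resp_mod_frac * resp`, the ECG is a Gaussian-bump template train
(P-QRS-T with a dominant R deflection, which is all a QRS detector needs),
and the PPG is a pulse train lagging the R peaks by `ppg_delay_s`. Additive
white Gaussian noise (`noise_sd`) is applied after the truth is recorded.

`simulate_cohort()` draws subject parameters uniformly from ranges whose
defaults are mean ± one SD of typical catheterised ICU cohort vitals
(heart rate 89 ± 17 bpm, PAP 42 ± 13 / 22 ± 8 mmHg, ABP 117 ± 23 /
60 ± 15 mmHg, respiratory rate 20 ± 7 /min). These ranges describe a
plausible cohort, not any particular patient population; CVP (4–12 mmHg)
and pulse-arrival delay (0.15–0.3 s) use textbook values.

What the simulator deliberately does **not** model: arrhythmia, valve and
structural disease, pulse-transit-time physics, sensor artifacts beyond
additive Gaussian noise, or inter-channel amplitude relationships beyond the
shared latent state. Passing tests therefore demonstrate that the pipeline
is *correct* (it recovers what is recoverable by construction), not that it
achieves any particular accuracy on real recordings.

## Preprocessing and segmentation

The band-pass stage is a 0.5–50 Hz fourth-order Butterworth applied
forward-backward (zero phase, so no group delay is introduced between
channels), with odd-reflection edge padding so the slow 0.5 Hz pole's
start-up transient decays inside the pad rather than in the signal. The
0.5 Hz high-pass removes baseline wander; 50 Hz removes mains/monitor
noise while leaving the cardiac band untouched.

Windows are cut in index units — `window_samples = round(125 * window_s)`,
start indices at multiples of `round(125 * step_s)`, half-open — so no
floating-point drift accumulates over long records. Window lengths of
0.5–5 s and steps of 0.1 s up to the window length are supported. Windows
that touch samples flagged in the record's quality mask (missing values in
the source, interpolated on read) are dropped: conservative and
deterministic. Inputs are not amplitude-normalized per window by default.

Dataset splits are by *patient* (`split_by_patient()`): validation and test
receive `round(n * fraction)` subjects each (at least one when the fraction
is positive) and the remainder trains, so a 180-subject cohort at
0.8/0.1/0.1 gives 144/18/18. No subject ever contributes windows to two
sets, and the training surface refuses train/validation sets that share
patients.

## Wavelet representations

**Target representation.** The coefficient-mode regression target is the
maximal overlap (undecimated) discrete wavelet transform of the PAP window
with the Symlet-4 wavelet at level 6: detail bands D1–D6 plus the
approximation A6, i.e. 7 bands × `window_samples` coefficients (1750 for a
2-s window). Level 6 is the unique choice that yields seven bands with this
coefficient count. Boundary handling is circular, which keeps the transform
*exactly* invertible (`modwt_reconstruct()`) and energy-preserving on
finite windows; the tests cross-check the time-domain pyramid against an
independent frequency-domain implementation and assert reconstruction below
1e-8 relative error. A window must be at least as long as the level-6
filter support (225 samples); shorter windows may use a lower level or the
direct waveform target.

**Input features.** `scattering_features()` computes a Gabor wavelet
scattering transform: analytic Gaussian band-pass filters (quality factors
Q = 8 for the first cascade stage and Q = 1 for the second, geometrically
spaced from just below the Nyquist frequency down to the invariance
cutoff), modulus after each stage, with second-order paths restricted to
frequency-decreasing pairs. Path outputs (a zeroth-order low-pass path,
first-order moduli, second-order moduli) are averaged by Gaussian low-pass
filters and subsampled to a fixed frame grid (~8 frames/s). The tensor's
channel dimension holds `n_filterbanks` (default 4) dyadically spaced
averaging scales `T, T/2, T/4, T/8` with `T` = half the window length by
default: the coarsest channel carries translation-invariant energy, the
finer channels trade invariance for temporal resolution. This multi-scale
reading of the "channels" axis is a design choice; the feature dimension is
consequently configuration-dependent and reported in the tensor's layout
metadata (`m` paths × `n` frames) rather than hard-coded.

Three properties are enforced by tests: zero input maps to zero features;
features are positively homogeneous (scaling the input by `a > 0` scales
every coefficient by `a`, exactly in floating point); and at the invariance
scale a 40 ms circular shift moves the features by less than
`shift / invariance_scale` in relative L2 norm.

## Regression models

Eleven families share one surface (`model_spec()` / `train()` /
`predict_pap()`): generalized linear regression, ridge, lasso, SGD linear,
support vector regression, k-nearest-neighbours, Gaussian process
regression, random forest, extremely randomized trees, gradient-boosted
trees, and the residual CNN. One-dimensional families receive the flattened
feature vector; multi-output targets are handled by one regressor per
output with shared hyperparameters (ridge and the linear families solve all
outputs in one closed-form system). Input mode is `raw` (flattened signal
windows) or `scattering`; output mode is the PAP waveform directly or its
flattened MODWT coefficients, reconstructed through the inverse transform at
prediction time. By convention raw inputs pair with waveform output and
scattering inputs with coefficient output, mirroring the two comparison
arms; windows shorter than the level-6 support fall back to the waveform
target.

The residual network (`build_resnet()`) is a 1-D adaptation: convolutions
run along the feature axis with signals × channels as input planes. It
comprises a stem convolution (kernel 7, stride 2), 16 bottleneck residual
blocks (1×1 reduce, kernel-3, 1×1 expand, identity shortcut at constant
trunk width — so shortcuts contribute no convolutions), a 1×1 pre-head
convolution, global average pooling, dropout and a linear head; that is
exactly 50 convolutional layers by introspection
(`count_conv_layers()`), making the architecture claim checkable rather
than nominal. Training is mean-squared-error minibatch SGD with momentum
and inverted dropout, implemented on plain matrices with an explicit
backward pass (verified against numerical differentiation), single-threaded
and deterministic given the seed. The default test profile uses a reduced
network (4 blocks, width 16); the 16-block network is constructed and
introspected but not trained in the routine suite, purely a problem-size
choice for the desk-scale experiments below.

`grid_search()` scans learning parameters (dropout 10–50%, learning rate
0.0001–0.001 discretized as {1, 2.5, 5, 10}·1e-4, batch size 8–128, epochs
1–5 are the intended axes) and selects by validation R²; ties break by
smaller validation MSE, then grid order. `run_comparison()` crosses model
families, window/step sizes, feature modes and signal sets
(three noninvasive vs all five) and reports the five waveform metrics per
combination on the held-out test patients, with the input signals recorded
in each row as provenance.

## Per-beat pressures

`detect_qrs()` is an energy-threshold detector of the Pan-Tompkins family:
band-limit to 5–15 Hz, differentiate, square, integrate over 150 ms,
threshold at a fixed fraction of the integrated peak (relative, so the
detections are invariant to ECG rescaling), 200 ms refractory period, and
refinement to the dominant band-limited deflection. `find_extrema()`
returns strict local maxima/minima with plateaus attributed to their
leftmost sample. `extract_sbp_dbp()` takes the ECG beat count `n` and
selects the `n` *highest peaks* as systolic and the `n` *lowest valleys* as
diastolic pressures, re-sorted by time — the only reading under which
valley amplitudes are diastolic pressures. When the waveform offers fewer
extrema than beats the available ones are returned with a count-mismatch
warning (a policy choice; equality cannot be assumed on noisy estimates).
The returned lists are time-ordered but not claimed to be matched
one-to-one with specific QRS complexes.

## Evaluation

Waveform metrics use the standard definitions: R² = 1 − SS_res/SS_tot,
explained variance EV = 1 − Var(residual)/Var(truth) (EV ignores systematic
bias, so R² ≤ EV always — a tested invariant), MSE, MAE, and MAPE reported
as a percentage with zero targets excluded under a warning. Per-beat
agreement reports MD, MAD, MAPD, SD of differences and CP5 (percentage of
beats within 5 mmHg).

Confidence intervals are percentile bootstrap (the simplest two-sided
choice) with the *window* as the default resampling unit — the model's
sample unit — with sample- and patient-level alternatives available. The
reference replication count is 20,000; the test suite and acceptance script
use 500–2,000 replications, a problem-size choice that leaves the
percentile interval stable at the tolerances tested. On a Gaussian toy
(200 paired samples, noise SD 2, analytic MSE 4) the empirical coverage of
the nominal 95% interval over 500 Monte-Carlo repeats is ~93–95%.

## Numerical and design notes

* All randomness flows through explicit seeds; seeded helpers save and
  restore the caller's RNG state.
* MODWT circular boundary handling trades physical edge realism for exact
  invertibility; windows are short enough (≤ 5 s) that this is the right
  trade for a reconstruction target.
* The scattering configuration that would reproduce any particular printed
  feature-map shape is not a contract; dimensions are derived from
  (window length, configuration) and carried as metadata.
* Degenerate inputs: constant targets make R²/EV undefined (error), flat
  ECG yields zero detections with a warning, records shorter than one
  window yield an empty window set with a warning, sub-support windows are
  rejected with the maximal admissible level suggested.
* Desk-scale problem sizes used throughout the tests and the acceptance
  script: cohorts of 6–50 subjects at 10–26 s per record, a 20-subject
  noiseless cohort for the recovery experiment, and a 180-subject cohort
  (3 s records) for the split arithmetic. These sizes are the package's
  own test conditions; the pipeline itself has no such limits.

## Known limitations

Synthetic validation bounds what can be claimed: the regression recovery
experiments fix the pressure amplitudes across the cohort so that PAP is a
deterministic function of the observable latent state — the honest upper
bound for what waveform regression can do. With amplitudes varying freely
and no coupling between PPG amplitude and PAP (as in the default cohort
ranges), cross-patient amplitude prediction is unidentifiable from the
three noninvasive channels alone, and test R² drops accordingly; that
behaviour is expected, not a defect. Real-data performance additionally
depends on artifact handling and inter-patient physiology not modelled
here.
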
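---
title: "Band-power EEG screening for Parkinson's disease: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power EEG screening for Parkinson's disease: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Resting-state scalp EEG shows reproducible spectral shifts in Parkinson's
disease: slow-band (theta) power tends to rise while fast-band (beta, gamma)
power falls relative to healthy controls. `pdeeg` implements a complete
screening pipeline built on that observation: filter a multichannel
recording into the five canonical frequency bands, summarise each 1-second
epoch of each channel by its Welch band power, and classify epochs either
with a per-band linear SVM baseline or with a compact 2D convolutional
network that reads all five bands at once as a bands-by-channels map.

Two acquisition geometries are supported as presets: `dataset1` (32
channels at 512 Hz, first 180 s analysed, i.e. 180 epochs per recording,
patients recorded twice — once on and once off medication) and `dataset2`
(29 channels at 500 Hz, first 120 s, one session per patient). Three
binary contrasts are defined on them: `case1` = medicated patients vs
controls and `case2` = unmedicated patients vs controls on `dataset1`,
`case3` = patients vs controls on `dataset2`.

Because clinical recordings cannot ship with a package, `pdeeg` includes a
first-class synthetic cohort generator that plants the group structure the
classifiers are meant to exploit. Every stage — file I/O, filtering, ICA,
segmentation, spectral estimation, the two model families and the
cross-validation harness — is exercised end to end on generated cohorts.

# Pipeline and models

## Preprocessing

1. **Crop** to the preset analysis window (first 180 s or 120 s).
2. **Broadband filter** 0.5–50 Hz: Butterworth band-pass designed from the
   analog prototype (lowpass-to-bandpass transform, bilinear transform with
   edge prewarping, second-order sections) and applied forward and backward
   (zero phase, length preserved). The per-pass order is 6: with the
   forward-backward squaring this keeps the passband within about 0.5 dB
   away from the edges and attenuates 60 Hz mains by more than 20 dB,
   which a 4th-order pass cannot do; one octave outside the edges the
   attenuation exceeds 50 dB.
3. **ICA artifact removal** on the broadband recording, before band
   decomposition. Symmetric FastICA (tanh contrast, as many components as
   channels) is run with a deterministic seed; components whose absolute
   Pearson correlation with either frontopolar channel (Fp1, Fp2 — the
   ocular proxies) reaches the threshold (default 0.8) are zeroed before
   reconstruction. Convergence is declared on the usual unmixing-matrix
   criterion *or* when the contrast objective stalls: EEG-like synthetic
   data contain a rotationally degenerate near-Gaussian subspace in which
   the unmixing matrix never settles even though every identifiable
   component has. Non-convergence is retried once from a second
   deterministic start, then raised as an error.
4. **Band decomposition** into delta 1–4, theta 4–8, alpha 8–13, beta
   13–30 and gamma 30–48 Hz (half-open intervals `[low, high)`, so shared
   edges belong to exactly one band). The gamma band stops at 48 Hz even
   though the broadband filter reaches 50 Hz, keeping a guard band below
   mains frequencies.
5. **Segmentation** into contiguous, non-overlapping 1-s epochs taken from
   the start of the recording (exact tiling; concatenating the epochs
   reproduces the cropped signal bit for bit). Controls are labelled 0,
   patients 1.

## Spectral features

Per epoch and channel, the power spectral density is estimated by Welch's
method: Hann-windowed segments of half the epoch (window 256 samples at
512 Hz), 50% overlap — three averaged segments per 1-s epoch on a 2 Hz
grid, the coarsest grid on which delta (1–4 Hz) still owns a bin. One-sided
density scaling is used, so integrating the spectrum over frequency
recovers the mean squared amplitude; with a single rectangular full-length
window the estimator reduces exactly to the plain periodogram (a test
asserts this equivalence at 1e-10 relative).

The band summary is the **mean** density over in-band bins (not the sum),
which makes features invariant to grid resolution. Powers are kept raw
(no log transform) before standardization, matching the reference
protocol; `log_power` is exposed as a flag. Per-band feature matrices are
epochs x channels; the stacked layout concatenates the five band blocks
band-major, so each row reshapes losslessly to a 5 x channels map
(160 columns for 32 channels, 145 for 29).

Standardization is per-column z-scoring **fitted on training rows only**
and applied unchanged to held-out rows; zero-variance training columns map
to zero with a warning. Inside every cross-validation fold the scaler is
refitted on that fold's training side.

## Classifiers

* **Linear SVM baseline** (per band): L2-regularised hinge loss, solved by
  dual coordinate descent (the liblinear algorithm) with C = 1 and a bias
  column. Decision margins are exposed for ROC analysis; reported
  probabilities are logistic-squashed margins.
* **Band-stacked 2D CNN**: input oriented channels x bands so that the two
  2x1 max-pools halve the channel axis (32 -> 16 -> 8; odd sizes floor).
  Two 3x3 same-padding convolutions with ReLU (16 and 32 filters), one
  ReLU fully-connected layer (64 units), one sigmoid output. Trained with
  Adam (learning rate 1e-3, batch 32, up to 30 epochs) on binary
  cross-entropy, with a stratified 10% validation split and early stopping
  at patience 5. Implemented as im2col + BLAS matrix products with
  hand-written backpropagation (verified against finite differences);
  training is bit-reproducible under a fixed seed on one device.
* **Per-band 1D CNN** (ablation): the same depth and pooling scheme on a
  single band's channel vector (3x1 kernels, 2x1 pools).

The published layer list implies a pooled shape of 8 x 5 for 32 channels
(32 halves twice); the printed "16 x 5" after two 2x1 pools is not
reachable under any standard padding, so the implementation follows the
layer list. Probability 0.5 is a tie broken toward the patient class.

## Evaluation

Two fold schemes are provided. **Subject-dependent** folds are stratified
at the epoch level (a subject's epochs may sit on both sides of a fold) —
the optimistic protocol under which headline accuracies are usually
reported. **Subject-independent** folds group by subject, default
leave-one-subject-out; both sessions of a dual-session patient travel
together, and a leak check runs on every invocation, not only in tests.
The SVM protocol is reported via k-fold cross-validation by default (the
9:1 stratified holdout is also implemented, matching the published split
sizes 5022/558 on 5580 epochs). Metrics per fold: confusion counts
tallied directly, sensitivity TP/(TP+FN), specificity TN/(TN+FP),
precision, F1, and AUC by trapezoidal integration of the ROC swept over
unique score values (equal to the normalised Mann–Whitney statistic; a
test asserts the equivalence). Fold summaries are unweighted means.

# The synthetic cohort generator

Each channel is a sum of five band-limited Gaussian-noise oscillations
(white noise Fourier-masked to the band, unit RMS), 1/f-power "pink"
background shaped over 0.5–50 Hz, white sensor noise, and stereotyped eye
blinks. Band-limited noise rather than pure tones keeps Welch estimates
realistically variable — pure sinusoids would make classification
trivially easy.

Defaults state a plausible resting cohort and are not tuned to tests:
oscillation amplitudes (delta 6, theta 5, alpha 10, beta 3, gamma 1.5 uV)
follow the usual alpha-dominant resting spectrum with weak gamma; pink and
white noise at 4 and 1 uV RMS; blinks at 12/min (spontaneous rates are
roughly 8–20/min) with 80 uV peaks on Fp1/Fp2, 300 ms raised-cosine
bumps at Poisson times, attenuated exponentially with scalp distance from
the frontal pole elsewhere (approximate 2D montage coordinates; not
anatomically exact). The patient effect is multiplicative per band —
defaults theta x1.5, beta and gamma x0.7 — encoding the published
direction (theta up, fast bands down); the magnitudes are free parameters
chosen for testability, since no effect sizes are published for the
reference cohorts. Medicated sessions (PD_ON) use multipliers pulled
halfway back toward 1; no quantitative on/off contrast is published, so
"halfway" is a modelling choice. Single-session `dataset2` patients carry
the group value `"PD"` (medication unspecified) and full multipliers.

Subjects differ through log-normal random effects drawn once per subject
from a substream keyed by the master seed and the subject id (cohorts are
therefore extensible without reshuffling existing subjects, and both
sessions of a patient share their subject traits): a per-band amplitude
effect (SD `subject_sd` on the log scale) *and* a fixed per-channel gain
profile at half that SD — an individual topography. The second component
is what makes subjects recognisable to epoch-level classifiers: with a
purely scalar per-subject effect, subject identity lies along a common ray
in feature space and epoch-level (subject-dependent) cross-validation
cannot exploit it, so the well-known optimism of subject-dependent
protocols would not reproduce. With the topography term, high
`subject_sd` yields the expected gap: epoch-level folds stay accurate
while leave-one-subject-out collapses.

Because power scales with amplitude squared, the realised patient/control
band-power ratio converges to the squared multiplier; a test checks this
within 10% at 50 subjects per group.

What the generator does **not** emulate: volume conduction and realistic
inter-channel correlation structure, non-stationarity (drowsiness, eye
closure), muscle and line-noise artifacts, heavy-tailed amplitude
distributions, or any disease physiology beyond stationary band-power
shifts. A green planted-effect test therefore establishes that the
pipeline recovers spectral group structure it was pointed at — not that
it would reach any particular accuracy on clinical recordings, whose
published headline numbers additionally depend on unstated
hyperparameters.

# Numerical choices and degenerate inputs

* Filtering pads by odd reflection (three time constants of the low edge,
  capped at the trace length) before the forward-backward passes.
* Sections are ordered with poles farthest from the unit circle first;
  the delta band at 512 Hz (poles nearest z = 1) stays stable in double
  precision as second-order sections.
* Welch refuses windows longer than the epoch; bands with no bins on the
  frequency grid raise an error naming the resolution.
* Non-finite feature cells block serialization with a count; empty
  feature matrices round-trip as header-only files.
* EDF output quantises to 16 bits over each channel's span; recordings
  shorter than one 1-s record are refused.
* The SVM visits rows in one seeded shuffle, making the solve
  deterministic; ICA and CNN initialisation draw from substreams of the
  master seed so stages can be re-run independently.
* A single master seed fans out to simulation, ICA, fold assignment and
  per-fold training; artifact trees contain no timestamps and reruns are
  byte-identical.

# Known limitations

* The CNN trains on the CPU in R; minutes, not seconds, for full-size
  cohorts (the defaulted full demonstration fits inside ~15 min on one
  core; tests and the acceptance script run scaled-down cohorts).
* ICA rejection uses the proxy-correlation rule only; no automatic
  bad-channel handling, re-referencing or notch filtering (50/60 Hz lies
  outside the analysis band by construction).
* Subject-independent results on small cohorts are fragile by nature;
  the package reports them but the generator makes no claim that their
  absolute level matches any published table.
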
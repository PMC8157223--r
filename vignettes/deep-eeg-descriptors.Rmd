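---
title: "Deep convolutional descriptors for EEG biometric verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep convolutional descriptors for EEG biometric verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

EEG carries a stable individual signature: the distribution of spectral
power across frequency bands and electrodes differs between people and is
reasonably stable across recording sessions. `eegid` implements a deep
descriptor pipeline that turns 12-second windows of multi-channel EEG into
fixed-length feature vectors and evaluates how well those vectors verify a
claimed identity.

The pipeline has five stages:

1. **Preprocess** — select electrodes and zero-phase band-pass filter the
   whole recording (the gamma band, 30–50 Hz, is the default; 1–50 Hz and
   10–30 Hz are also provided).
2. **Segment** — cut 12-s windows (1,920 samples at 160 Hz). For training,
   a sliding window with a constant stride (default 40 samples = 250 ms)
   produces a heavily augmented set; for testing, windows never overlap
   (5 per 60-s baseline, 10 per 120-s task).
3. **Train** — a 1-D CNN classifies the training subjects (closed gallery)
   with SGD: momentum 0.9, mini-batches of 100 reshuffled per epoch, and a
   learning rate of 0.01 for 2 epochs then 0.001 for 18.
4. **Embed** — the classification layers (dropout, FC4, softmax) are
   removed and the penultimate fully-connected layer (FC3) becomes the
   descriptor: 256 dimensions for architecture A, 4,096 for B.
5. **Verify** — all pairs of test embeddings are scored with a distance;
   pairs from the same subject are genuine, others impostor. Sweeping a
   threshold gives the DET curve; the package reports the equal error rate
   (EER, where false acceptances balance false rejections) and Daugman's
   decidability d' = |mu_imp − mu_gen| / sqrt((var_imp + var_gen)/2).

## Architectures

Architecture A: three valid (no padding) temporal convolutions with kernels
11, 9, 9 and stride 1, each followed by max-pooling (size 2; strides 4, 2,
2), then FC1–FC4 with a 10% dropout before the softmax. On a 1,920-sample
window the temporal lengths are 1910 / 478 / 470 / 235 / 227 / 113.
Architecture B: five convolutions (kernels 51, 17, 7, 7, 7) with size-2
stride-2 pooling, ending at 52 samples after pool5.

The canonical geometry fixes kernels, pooling and the FC3 width; filter
counts and FC1/FC2 widths are configurable (defaults 96/128/256 and
4096/1024 for A). Electrodes are the input channels of the 1-D convolution;
kernels span all channels and slide along time. Convolutions and FC1–FC3
use a rectifier; making FC3 linear was tried and rejected (it collapses
FC3·FC4 into one linear map and measurably hurts both accuracy and
verification). Weights are seeded scaled-uniform (fan-in) draws; forward
and backward passes for the conv layers are compiled (RcppArmadillo), and
every gradient path is validated against central differences in the tests.

Squeeze-and-excitation (SE) variants insert channel-attention blocks:
squeeze is the per-channel temporal mean; excitation maps it through a
bottleneck of width `max(1, floor(C/r))` with a rectifier and back with a
logistic squashing, and the input is rescaled channel-wise by the resulting
gates in (0, 1). Variant 1 replaces each convolution by an SE
recalibration (pooling retained — the source description is ambiguous and
this is the interpretation we implement); variant 2 gates the raw
electrodes; variant 3 sits after the last pooling; variant 4 combines 2 and
3; variant 5 follows every convolution. The reduction factor r takes
values 2^x, x = 0..5.

## The synthetic study generator

Real multi-session EEG cannot ship with the package, so `synth_config()` /
`synthesize_recording()` generate studies whose identity structure is
controllable. Each subject's fingerprint has two stable components, both
scaled by `separability`:

* **band amplitudes** — per-channel sinusoid amplitudes in the three
  analysis bands, log-normal around `base_amplitude` (1 µV, the scale of
  narrow-band scalp rhythms) with log-SD `0.15 × separability`. At
  separability ≈ 3–5 this is a tens-of-percent to ~2× inter-individual
  band-power spread, which is what real EEG shows; early versions of the
  generator used a much larger coefficient and produced 10-fold
  cross-channel dynamic ranges that are neither realistic nor trainable
  with a fixed SGD recipe.
* **spectral peak positions** — each band has `n_sinusoids = 3` peaks
  jittered per subject around a study-wide base set with SD
  `separability` Hz, wrapped around the band edges so peaks never pile up
  at the boundaries. Individual peak frequencies are a stable trait of
  real EEG.

Each peak is rendered as a ~1 Hz-wide cluster of grid sinusoids with random
phases per (subject, task, run, channel), so the rhythm decoheres within a
couple of seconds the way real band-limited EEG does. This matters: with
fully coherent sinusoids a CNN simply memorizes the training session's
waveform and cross-session verification collapses. Frequencies sit on the
1/60 Hz grid (integer cycles over 60 s and 120 s sessions), so a
full-record periodogram concentrates each component in one bin — the
property the band-leakage tests rely on.

Task effects are multiplicative band perturbations composed of a study-wide
effect (the same task perturbs everyone alike, log-SD `task_shift_sd` =
0.02) plus a subject idiosyncrasy scaled by `separability` — at
separability 0 no identity leaks through task shifts, and the package
asserts that between- and within-subject band-power distances are then
statistically indistinguishable. White Gaussian noise (`noise_sd` = 0.2 µV)
is added throughout. Sessions mirror the motor movement/imagery layout:
60-s EO/EC baselines, 120-s tasks T1–T4 with three runs, 160 Hz, and the
standard 64-electrode montage (or its 9-electrode frontal/motor/occipital
subset).

What the generator does **not** model: 1/f background, artifacts (EOG/EMG),
electrode geometry and volume conduction, non-stationarity beyond task
shifts. Passing tests on synthetic data therefore demonstrate that the
pipeline's machinery is correct and that it can extract a spectral identity
signal — not that the reported real-data error rates are reproduced.

## Numerical choices

* Filtering is zero-phase FIR (Hamming design, forward–backward), applied
  to the whole recording before segmentation so window interiors see no
  transient. The order adapts to the band's lower edge (transition =
  `low_hz/2`, ~3.3/transition-width taps, capped at 512 for the 1-Hz edge
  of the broad band); the filtfilt pass doubles the stopband attenuation,
  giving well over 40 dB one octave outside the passband.
* Window counts use `floor((L − W)/s) + 1` with the first window at sample
  0 — this reproduces the published 889/905 counts for 123/125-s records
  at stride 20. (The published per-subject count of 384 baseline segments
  is inconsistent with this formula, which gives 385; we treat the formula
  as authoritative.)
* The chronological 90/10 split takes the first `ceil(0.9 n)` segments per
  subject for training; validation is the tail, and pipelines skip
  validation when a tiny study leaves the tail empty.
* The EER is located by sweeping all distinct distances (FAR = fraction of
  impostor distances ≤ t, FRR = fraction of genuine > t) and linearly
  interpolating (FAR+FRR)/2 at the crossing; ties take the smallest
  threshold. Decidability uses sample variances.
* Scoring uses Euclidean distance on raw embeddings by default; cosine is
  available behind a flag (`metric = "cosine"`), and the scaled synthetic
  check below uses it.
* Mini-batch softmax/cross-entropy gradients are averaged over the batch;
  max-subtraction stabilizes the softmax; argmax ties break to the first
  class.

## The scaled synthetic verification check

The published error rates (sub-1% EERs on 109 subjects) require the full
Physionet dataset and full-scale training; the package instead verifies the
end-to-end property on a scaled synthetic study chosen to fit a single CPU:

* 10 subjects, 9 electrodes, separability 5 — "high separability" sized
  against the ~25% relative noise of a 12-s band-power estimate (roughly
  the 5:1 signal-to-nuisance regime), stride 20, EO for training, EC for
  testing;
* architecture-A layer geometry with reduced widths (8/12/16 filters,
  FC 4096→64, 1024→32, embedding 32) — the full-width network neither fits
  the time budget nor is needed for the property;
* the standard recipe otherwise (20 epochs, momentum 0.9, lr 0.01×2 +
  0.001×18), with mini-batches of 25 — scaled with the gallery exactly as
  the data volume is (the published batch of 100 served 109 subjects);
* cosine scoring of the test embeddings: softmax training separates
  classes by direction, and at small gallery size the directional metric
  is the stable readout of the same information.

Under these conditions training converges to essentially perfect
closed-gallery accuracy and the cross-session EER lands in the low
percents, while permuting the test identities pushes the EER to chance
(~50%) — together showing that the verification signal comes from learned
identity structure and not from any leak in the pipeline. The tests also
sweep all five SE variants across r ∈ {1, 2, 4, 8, 16, 32} end to end at
small scale to pin the shape contracts.

## Known limitations

* Training is single-threaded CPU R/RcppArmadillo; it is meant for
  method-scale studies and tests, not for the full 109-subject dataset.
* The generator's identity model is spectral only; methods that exploit
  temporal morphology would not be differentiated by it.
* SE variant 1 follows one reading of an ambiguous description (SE blocks
  replace convolutions, pooling kept).
* EDF support covers the 16-bit single-rate layout used by the motor
  movement/imagery distribution, not the full EDF+ feature set.
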
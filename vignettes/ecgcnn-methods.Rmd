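---
title: "Methods: lightweight 1D CNNs for single-lead ECG arrhythmia detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lightweight 1D CNNs for single-lead ECG arrhythmia detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Single-lead electrocardiograms from wearables are short, noisy and
scale-inconsistent across devices, yet carry enough information to separate
normal sinus rhythm from common arrhythmias (atrial fibrillation, premature
atrial and ventricular beats).  `ecgcnn` implements a complete detection
pipeline around two small one-dimensional convolutional networks:

* a **binary** network (Normal vs. Arrhythmia) for 30-s smartwatch-style
  segments: four same-padded ReLU `Conv1D` layers with 16/32/64/128 filters
  and kernels 11/13/15/17, each followed by a max-pool of size 3 and stride
  2, so a 1000-sample window shrinks 1000 → 499 → 249 → 124 → 61 and
  flattens to 7,808 features; then dropout, a 128-unit ReLU dense layer and
  a 2-unit softmax head.  1,176,866 trainable parameters.
* a **multiclass** network for beat-annotated Holter records (classes N, L,
  R, A, V): the same conv stack but pool size 2, the first pool with
  stride 1 and the rest stride 2 (1000 → 999 → 499 → 249 → 124, flatten
  15,872), then dropout, dense 35 (ReLU), dense 5, softmax.  732,791
  parameters.

The pooling schedules are the unique simple configurations consistent with
the printed length chains and flatten widths above: a uniform pool-2/
stride-2 schedule would give 500/250/125/62, not 999/499/249/124, so the
first multiclass pool must use stride 1; likewise 499/249/124/61 forces
pool 3, stride 2, valid padding throughout the binary stack.

All training uses categorical cross-entropy with Adam (learning rate 0.001,
the backend default, as the protocol names the optimizer but not the rate),
batch size 32, and 50 epochs by default.  Dropout defaults to 0.5; the rate
is not stated by the protocol and 0.5 is the conventional choice for dense
heads of this size.

## Preprocessing chain

Five stages, applied in order:

1. **Baseline-wander removal** — a 4th-order Butterworth high-pass at
   0.5 Hz on the continuous signal.  We apply it forward–backward
   (zero-phase), because the pipeline is offline and linear-phase filtering
   preserves QRS morphology; the effective magnitude response is the
   squared single-pass response, which rejects DC below 1e-6 and a 0.05 Hz
   tone below 1e-3 while passing 5 Hz within 1%.  Naive forward–backward
   filtering leaves large edge transients at this cutoff (the impulse
   response spans hundreds of samples), so the implementation extends both
   ends by odd reflection and starts each pass from step-matched initial
   conditions.
2. **Wavelet denoising**, per extracted window — a periodized sym4
   discrete wavelet transform to the maximum level admitted by the window
   length, `floor(log2(N / (support - 1)))`, i.e. level 7 for N = 1000.
   Within each detail level the threshold is 0.04 × the level's maximum
   absolute coefficient; coefficients below it are zeroed (hard
   thresholding — "filtered with a fixed threshold" read as removal; soft
   shrinkage is available behind `preprocess_config(soft_threshold=)`).
   Approximation coefficients are untouched.  Because sym4 is orthogonal,
   the periodized transform round-trips exactly, so a zero threshold is the
   identity — a property the tests exercise at many lengths.
3. **Z-scoring**, per window, with the population standard deviation.
   Per-window (rather than per-record) standardization is the only choice
   that guarantees scale invariance across devices after windowing; a
   constant window maps to zeros by definition.
4. **Segmentation** — consecutive non-overlapping 1000-sample windows
   (≈ 7.81 s at 128 Hz) from sample 0; a trailing remainder is dropped, and
   windows whose span contains a noise marker are excluded.  No overlap or
   stride is used because the protocol never mentions one.
5. **Class coding** — beat-annotated windows take the majority beat symbol,
   with ties broken in favor of the non-N symbol and then the fixed order
   L < R < A < V (the protocol says only that windows are labeled from the
   beat annotations; the tie-break makes multi-beat windows deterministic).
   Windows containing unclassifiable beats are rejected.  Multiclass labels
   become length-5 one-hot vectors in the order (N, L, R, A, V); segment
   codes 0.0/1.0/2.0/3.0 collapse to (Normal, Arrhythmia) length-2 vectors
   with 1.0–3.0 all mapping to Arrhythmia.

Whether denoising runs before or after segmentation is ambiguous in the
source protocol (the wavelet is described per 1000-sample window, but the
stage list puts segmentation last).  We remove baseline on the continuous
signal and denoise/standardize per window, which satisfies both statements.

Records whose native rate differs from 128 Hz are resampled before
everything else by a polyphase windowed-sinc resampler (10 taps per phase,
Hamming window, exact group-delay compensation) with annotation indices
rescaled by the rate ratio; the resampler is written in the package because
the available `signal::resample` leaves a residual fractional delay and a
~9% gain error that would misalign annotations.

## The training engine

No deep-learning framework is available to R in this package's dependency
footprint, so the engine is part of the package: conv layers are evaluated
as im2col gathers followed by BLAS matrix products, with valid max-pooling
(first-maximum tie-break), inverted dropout, Glorot-uniform initialization,
reverse-mode gradients, and Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-7).  All
randomness — initialization, epoch shuffling, dropout masks — draws from a
single R RNG stream per fit, so a (data, seed) pair reproduces the model
bit-for-bit.  The realized parameter tensors are required to match the
analytic `count_parameters()` total exactly, and the tests compare the
engine's per-layer output shapes against `propagate_shapes()` layer by
layer.

FLOPs are reported under the documented 2 × MAC convention (conv:
`2·out_len·kernel·in_ch·out_ch`; dense: `2·in·out`; bias, pooling and
activations ignored), which gives 58,830,080 for the binary network.
Published figures produced by unnamed profiler tools can differ by tens of
percent depending on what they count; the package reports only its own
convention and does not attempt to reverse-engineer others.

## Evaluation protocol

Splits are patient-level always: a grouped 80/20 holdout (patients
shuffled by seed, `ceiling(0.8 · P)` on the training side) and
leave-one-subject-out cross-validation as the headline protocol.  LOSO
metrics are computed on predictions pooled across folds rather than
averaged per fold, matching how single global numbers are reported for
such protocols and weighting every window equally.

The metric suite: per-class one-vs-rest sensitivity, specificity and
accuracy; global accuracy (trace over total), macro-averaged sensitivity
and specificity; F1 with the Arrhythmia class positive in binary mode and
macro averaging otherwise; AUROC as the tie-corrected rank statistic
(`P(s⁺ > s⁻) + ½P(s⁺ = s⁻)`), binary-positive or macro one-vs-rest.  95%
bootstrap confidence intervals for AUROC and F1 resample evaluated windows
with replacement (default B = 1000); degenerate single-class resamples are
redrawn and counted, and a truth set with only one class yields an NA
interval rather than an error.

Class balancing (`balance_classes()`) oversamples minority classes with
replacement to the majority count, touching only multiplicity, and is
applied to training folds only — resampling test data would bias the
metrics.

## Grad-CAM for time series

`gradcam_map()` implements standard 1D Grad-CAM: channel weights are the
temporal mean of `∂(class logit)/∂A_k` at a conv layer (the last conv layer
by default), the map is `ReLU(Σ_k w_k A_k)`, linearly interpolated to the
input length and normalized by its maximum, with an explicit flag for
identically zero maps.  The map is invariant to positive rescaling of the
class's output weights.  For localization checks the tests read an
intermediate conv layer (the third), where the temporal resolution
(≈ 4-sample stride) is fine enough to resolve single QRS complexes; at the
last conv layer the 8-sample effective stride and the zero-padding edge
response dominate small maps.  Implementation correctness is pinned by a
closed-form test on a linear single-conv model.

## The synthetic cohort generator

`synth_cohort()` exists so every stage — including LOSO training — runs
without restricted or downloaded data.  Beats are sums of five Gaussian
bumps (P, Q, R, S, T) with physiological centers and widths; class
structure enters through the RR sequence and morphology: NSR draws RR
around 60/70 bpm with CV 0.03 and keeps P waves; AF uses CV 0.25 at
95 bpm with P suppressed; PAC/PVC are NSR with 15% premature beats (RR
× 0.62, compensatory pause × 1.35), atrial ectopics narrow and labeled A,
ventricular ectopics wide (QRS width × 2.5, P suppressed) and labeled V.
Baseline wander is a two-tone sinusoid below 0.5 Hz (0.2 mV) plus white
noise (0.03 mV).  Defaults are fixed once at these values as a realistic
resting-ECG regime; annotations are emitted by construction, not detected.
Patient seeds derive deterministically from the master seed, and class
mixes are apportioned by largest remainder.

What the generator does *not* emulate: real electrode-motion artifacts,
respiration-modulated morphology, inter-patient morphology variability
beyond RR/P/QRS parameters, or smartwatch-specific contact noise.  Passing
tests on synthetic cohorts therefore demonstrate pipeline and protocol
correctness — geometry, leakage-freedom, determinism, metric arithmetic,
directional effects of balancing — not clinical performance on real
devices.

## Problem sizes and numerical choices

The bundled study conditions keep everything desk-scale: the end-to-end
smoke experiment uses 8 patients × 64 s at 128 Hz (48 windows), LOSO over
8 folds at 10 epochs — a configuration a single CPU core finishes in a few
minutes — and the class-balancing comparison uses a fixed patient split of
an Arrhythmia-heavy 2:6 cohort trained for 6 epochs, mirroring the
imbalance regime of real smartwatch cohorts.  One pilot run fixed these
sizes; the ≥ 80% pooled-LOSO-accuracy smoke threshold was not adjusted
afterwards.  Tolerances follow the arithmetic: exact integer equality for
shapes and parameter counts, 1e-8 for wavelet round-trips, 1e-6 for
z-score moments and softmax row sums, 1e-9 for serialization round-trips
(16-bit WFDB quantization aside, which is bounded by half an ADC step at
gain 200).

Degenerate inputs are defined, not special-cased ad hoc: constant windows
z-score to zeros; empty or all-noise records contribute no windows;
single-class truth sets give NA AUROC and NA bootstrap intervals;
max-pooling ties resolve to the first maximum; window labels reject spans
with no beats or unclassifiable beats.

## Known limitations

* The engine is CPU-bound R; it is meant for desk-scale experiments and
  protocol work, not for training on the full 48-record Holter corpus at
  50 epochs (the architecture and protocol run verbatim, but budget hours,
  not minutes).
* The WFDB layer covers formats 16 and 212 with MIT annotations — enough
  for the reference corpus layout — not the full format zoo.
* Only the sym4 wavelet ships, since the protocol names it; the transform
  is written for that filter bank.
* Headline clinical metrics from restricted smartwatch data are out of
  scope by design; nothing in the package targets them.
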
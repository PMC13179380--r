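---
title: "Multimodal EEG-ECG stress detection: models, pipelines, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal EEG-ECG stress detection: models, pipelines, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stressfuse)
```

## The problem

Acute psychological stress leaves complementary traces in two physiological
streams. Centrally, EEG band power shifts: frontal theta (4-8 Hz) and beta
(13-30 Hz) rise while alpha (8-13 Hz) is suppressed. Peripherally, the
autonomic balance tilts sympathetic: heart rate rises while beat-to-beat
heart-rate variability (HRV) falls -- lower RMSSD and SDNN, and a higher
LF/HF spectral ratio of the RR tachogram. `stressfuse` implements a
three-class classifier (baseline/rest, stress, amusement) that fuses both
streams with a learned attention gate, together with the full signal
pipeline on each side and a synthetic-signal generator that makes every
stage testable without access to wearable-sensor datasets.

## Signal pipelines

**EEG.** 14-channel recordings at 700 Hz pass through (1) a zero-phase
(forward-backward) Butterworth bandpass, 0.5-45 Hz, order 4 per pass;
(2) common average referencing, which subtracts the instantaneous
across-channel mean (idempotent, and exactly zero-mean across channels
afterwards); (3) segmentation into non-overlapping 10 s epochs, each
treated as an independent sample, with trailing remainders discarded and no
epoch spanning two source segments; (4) ICA artifact removal; (5) per-band
Morlet continuous wavelet transforms for theta, alpha and beta; and
(6) per-band standardization whose parameters are fit on training data
only.

Each band's scalogram is computed on 128 log-spaced frequencies inside the
band, the squared magnitude is averaged across the 14 channels, the time
axis is reduced from 7000 samples to 128 bins by non-overlapping window
averaging, and `log(1 + power)` compression is applied. Stacking the three
bands in the fixed order (theta, alpha, beta) yields the 128 x 128 x 3
image the backbones consume (rows = frequency, columns = time).

**ECG.** Single-lead recordings at 700 Hz are bandpassed at 0.5-40 Hz
(fourth-order, zero-phase), R-peaks are detected with the Pan-Tompkins
stages (5-15 Hz bandpass, five-point derivative, squaring, 150 ms
moving-window integration, dual adaptive thresholds with a 200 ms
refractory period and search-back at 1.66x the running RR average, and
refinement to the local signal maximum within +/- 50 ms). RR intervals
outside (250, 2500) ms or deviating more than 30% from the median of their
five nearest neighbors are flagged and replaced by the local median of
unflagged neighbors -- a standard robust correction rule, marked in the
output so downstream consumers can see what was altered.

The 25-feature HRV panel concatenates three sub-panels in a fixed,
documented order: 10 time-domain features, 8 frequency-domain features
(cubic-spline interpolation of the RR series to a uniform 4 Hz tachogram,
Welch periodogram with 64 s Hann windows at 50% overlap, band powers over
VLF 0.0033-0.04, LF 0.04-0.15 and HF 0.15-0.4 Hz), and 7 nonlinear
features (Poincare SD1/SD2, sample entropy with m = 2 and r = 0.2 SDNN, and
DFA scaling exponents over box sizes 4-16 and 16-64).

## The model

Each modality is encoded by three convolutional backbones -- VGG16,
EfficientNetB0, and ResNeXt50-32x4d -- with their classifiers replaced by
global average pooling and a dense ReLU projection. For EEG, the three
512-wide projections are concatenated (1536) and reduced to a 512-dim
embedding `F_EEG`. For ECG, three 1-D conv blocks (64 filters/kernel
15/stride 2; 128/7/2; 256/3/1, each with batch norm, ReLU and max-pooling)
encode the raw 7000-sample segment; the resulting time x channel map is
read as a single-channel image, replicated to three channels, bilinearly
resized, and passed through the same three backbone architectures with
256-wide projections (768 concatenated). The HRV panel runs through a
25-64-128-256 MLP with ReLU and dropout 0.3. Raw (768) and HRV (256)
vectors are concatenated in that order and projected to the 512-dim
`F_ECG`.

Fusion is attention-based. Within each modality, the 512-dim embedding is
reshaped into 8 tokens of width 64 and scaled dot-product self-attention is
applied with learned token-wise Q/K/V maps and scale `1/sqrt(64)`:

    A_m = softmax(Q_m K_m^T / sqrt(d_k)) V_m,  d_k = 64.

Across modalities, a gate shared between the two embeddings -- a two-layer
perceptron (512-256-128) followed by a learned read-out vector
`w_a` of length 128 -- produces one scalar logit per modality, and a
two-way softmax yields convex weights:

    alpha_EEG = exp(w_a' MLP(F_EEG)) /
                (exp(w_a' MLP(F_EEG)) + exp(w_a' MLP(F_ECG))),
    alpha_ECG = 1 - alpha_EEG,
    F_fused   = alpha_EEG * A_EEG + alpha_ECG * A_ECG.

Because the gate is shared, identical inputs give exactly 0.5/0.5 and
swapping the modalities swaps the alphas. The classification head is
512-256-128-3 with He-normal initialization, batch norm, ReLU, and dropout
0.5 after each hidden layer, ending in a softmax over
{rest/baseline, stress, amusement}.

## Training protocol

Adam with beta1 = 0.9, beta2 = 0.999, eps = 1e-7; cosine-annealed learning
rate

    eta_t = eta_min + (eta_max - eta_min)(1 + cos(pi t / T_max)) / 2

with defaults eta_max = 1e-3, eta_min = 1e-6, T_max = 100; and
label-smoothed (eps = 0.1) categorical cross-entropy plus an L2 penalty
(lambda = 1e-4) on weights -- biases and batch-norm affine parameters are
excluded from the penalty, which is the usual convention. One printed
description of the base learning rate (1e-4) conflicts with the schedule's
own printed eta_max = 1e-3; the schedule parameters are taken as the
authoritative defaults, and any other base rate can be configured through
`schedule_config()`.

Splits are subject-independent: every subject is assigned to exactly one of
train (80%), validation (10%), test (10%). Counts follow largest-remainder
apportionment with ties broken in (train, val, test) order; for 35 subjects
this yields the canonical 28/4/3 partition. Input standardization
(scalogram bands, HRV features, raw ECG scale) is fit on the training split
only.

Augmentation operates on raw signals, before any preprocessing: Gaussian
noise with SD = 0.05x the per-channel signal SD, time warping with a factor
drawn from 0.9-1.1 (resample to `round(L / factor)` samples, then
center-crop or edge-pad back to the original length), amplitude scaling in
0.8-1.2, and -- for EEG only -- a random permutation restricted to mutually
non-adjacent channels under the fixed 14-channel montage's neighbor graph.
The training harness realizes augmentation by expanding the training split
with seeded augmented copies before preprocessing; the harness refuses
augmented records outside the training split, so validation and test sets
are never augmented. Batch size defaults to 32 (unstated in the protocol;
a common default), and the epoch budget is configurable with `T_max` as the
default.

## The synthetic generator

The generator exists so that every pipeline stage has ground truth. EEG
segments are sums of band-limited Gaussian processes (theta/alpha/beta)
whose variances encode the condition, 1/f background noise, optional 50 Hz
line interference, and optional blink transients (0.3-0.5 s half-sines with
a frontal-dominant, rank-1 topography) for the ICA stage to find. The
stress preset multiplies theta power by 1.3 (applied preferentially to
frontal channels), beta by 1.4, and alpha by 0.7. ECG is an
integral-pulse-frequency-modulation style RR process -- mean interval
60/(HR + shift) seconds, sinusoidal LF (0.1 Hz) and HF (0.25 Hz) modulators
plus white jitter -- rendered with a Gaussian-sum PQRST template, baseline
wander, and additive noise, returning ground-truth R-times. Stress adds
15 bpm, scales RMSSD-governing amplitudes by 0.6, and doubles the LF/HF
ratio; amusement is mild (alpha up 1.15x, +4 bpm, RMSSD 0.85x). These
moderate defaults are consistent with the stress-physiology literature's
qualitative signature; an `easy` preset with wider separation and tighter
subject variability exists for fast end-to-end training checks whose
purpose is to verify that the learning machinery recovers a known signal,
not to estimate realistic effect sizes.

What the generator does not emulate: volume-conduction mixing from real
cortical sources, non-stationary artifacts other than blinks, sensor
dropout, respiration coupling, or the label noise of real protocols.
Passing tests therefore demonstrate correctness of the computational
pipeline and learnability of planted condition structure -- not field
performance on wearable data.

## Numerical choices

- Morlet center frequency omega0 = 6, scales log-spaced within each band;
  the standard time-frequency trade-off for EEG work.
- The analytic Morlet filters are band-limited, so the inverse transform is
  synthesized at a decimated rate chosen per band (spectral folding with
  empty upper blocks); this is exact for the complex coefficients, and the
  power envelope is then averaged onto the 128 time bins.
- `log(1 + power)` compression precedes standardization because spectral
  power is heavy-tailed.
- The zero-phase Butterworth filters are applied as their exact squared
  magnitude response in the frequency domain (reflection padding,
  pole-zero-factored evaluation). Forward-backward filtering of an LTI
  design is mathematically identical to applying |H|^2; evaluating the
  response in factored form avoids the severe numerical error of the
  direct-form recursion when band edges sit near 0.001 of the sampling
  rate, making the operation exactly linear and its magnitude response
  analytic.
- ICA uses deflationary negentropy-maximizing fixed-point iteration
  (logcosh contrast) with a deterministic seed, preceded by targeted
  artifact extraction: the first component is fixed to the whitened
  regression direction of a 0.5-4 Hz frontal-average blink proxy (the
  direction whose time course best reproduces the proxy), and deflation
  runs on the orthogonal complement. Once a deflation component fails to
  converge, the remaining near-Gaussian subspace -- where rotations are
  unidentifiable anyway -- is completed orthonormally. Rejection policy:
  absolute correlation with the blink proxy above 0.7, or kurtosis above 8
  (a Gaussian source has kurtosis 3). On blink-free synthetic recordings
  the template component's proxy correlation stays near 0.5, safely below
  the 0.7 threshold; with blinks present it exceeds 0.8. Non-convergent
  recordings pass through unmodified with a warning and are marked in the
  report.
- The blink-proxy bandpass uses a second-order recursive design (stable at
  this narrow band), applied forward-backward.
- Population (divide-by-n) variance conventions throughout the HRV panel,
  so closed-form oracles are exact; pNN thresholds use strict inequality
  ("more than 50 ms").
- Degenerate cases: lf_nu/hf_nu are 0 when LF + HF = 0; sd2 is floored at
  0; sample entropy is NA-coded when no template matches exist; DFA alpha2
  is NA-coded when the series is too short for at least three usable box
  sizes.
- The 25-feature HRV panel needs at least 60 s of signal (VLF, DFA);
  10 s raw-path windows therefore pair with the panel of their 120 s
  parent recording window, which keeps the raw/HRV pairing while leaving
  every feature well-defined.

## Design decisions

- **Channel-to-image reduction.** The scalogram description admits two
  readings (channels as an image dimension vs. one plane per band). CWT
  power is averaged across channels per band, which preserves the stated
  128 x 128 x 3 shape; per-channel stacks are out of scope.
- **Per-band CWT.** Band separation precedes the transform (each band gets
  its own 128 log-spaced frequencies), rather than one broadband transform
  partitioned afterwards; this matches the stated processing table and
  gives each band full vertical resolution.
- **Token self-attention.** Self-attention over a single 512-dim vector
  requires a token structure; 8 tokens x 64 dims is used, with 64 matching
  the stated key dimension.
- **Gate MLP widths.** The printed "512-356-128" is treated as a
  typographical error for 512-256-128, consistent with the halving pattern
  used elsewhere in the architecture.
- **ECG raw-path share.** The 768-dim concatenation is split as 3 x 256
  (the per-backbone share is not stated).
- **1-D to 2-D reshape.** The conv-block output (time x channel) is taken
  as a single-channel image, replicated to 3 channels, and bilinearly
  resized to the backbone input size.
- **EEG reducer.** One shared dense 512 reducer after concatenation (not
  one per backbone).
- **Test profile.** Training the three canonical ImageNet trunks is not a
  CPU-scale exercise, so a `test` profile keeps the identical topology at
  reduced width: 64 x 64 scalograms, 128-wide projections and embeddings,
  8 x 16 attention tokens, compact trunks that keep each namesake's flavor
  (plain stacked convs; depthwise-separable with squeeze-excitation;
  grouped-conv residual). All structural and parameter-count checks run
  against the canonical `full` profile; training-behavior checks run on
  the test profile. End-to-end checks use a 10-subject easy-preset cohort,
  two segments per condition, 20 epochs.

## Known limitations

Real-dataset adapters load the package's portable CSV container (with
channel-count validation, label mapping, and polyphase resampling to
700 Hz); EDF ingestion is not bundled. The engine is single-threaded R on
BLAS; the full-size-profile model runs forward passes in seconds but is not
meant for full-scale training. Attention weights are exposed per sample for
interpretability, but no claim is made that they reproduce any empirical
attention distribution on wearable datasets -- that requires the external
data and full-scale training, which are out of scope here.
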
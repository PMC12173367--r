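---
title: "Dual-scale spectrogram classification of ECG heartbeats: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-scale spectrogram classification of ECG heartbeats: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecgbeatnet)
```

## The problem

Beat-level arrhythmia classification assigns each heartbeat of a
single-lead ECG to a rhythm class — here either the five AAMI EC57 beat
families (N, S, V, F, Q) used with 360 Hz Holter-style recordings, or
four merged rhythm groups (AFIB, GSVT, SB, SR) used with short 500 Hz
resting ECGs. The difficulty is threefold: recordings are noisy
(powerline interference, baseline wander, electromyographic noise),
classes are heavily imbalanced (normal beats typically dominate by a
factor of 10-100), and a beat's identity depends both on its own
morphology and on its rhythm context, i.e. the neighbouring beats.

`ecgbeatnet` addresses all three with a fixed pipeline: denoise, locate
R-peaks, cut each beat at two temporal scales, move both segments to the
time-frequency domain, oversample minority classes by Mixup, and train a
two-branch convolutional network with squeeze-and-excitation (SE)
channel attention whose branches see the two scales simultaneously.

## Signal conditioning

Denoising is wavelet shrinkage: an 8-level periodized Daubechies-4
decomposition, soft thresholding of every detail band with the
level-wise SURE (Stein's unbiased risk estimate) threshold, noise scale
estimated once from the median absolute deviation of the finest band.
The approximation band passes through untouched — slow baseline content
is the next stage's job. Signals are padded symmetrically to a multiple
of $2^{levels}$ and cut back, so length is always preserved; if a signal
is shorter than $2^{levels}$ the depth is reduced with a warning. We
implement the filter bank directly (the transform is orthogonal, and the
test suite checks exact reconstruction) rather than pulling in a
dependency for a 40-line computation.

Baseline wander is removed by subtracting a centered running median
whose window is 30 % of the sampling rate — 108 samples at 360 Hz. A
median, unlike a mean, ignores the QRS spikes entirely, so what remains
after subtraction is the beat train on a flat baseline. The window is
even; we define the even-window median as the mean of the two central
order statistics and use reflect padding at the edges, which avoids edge
spikes and keeps the operator deterministic. Constants are annihilated
exactly.

R-peak detection is a Pan-Tompkins-style detector: 5-15 Hz band-pass
(zero-phase), derivative, squaring, 150 ms moving-window integration, an
adaptive signal/noise threshold over integration peaks, and a 0.2 s
refractory period. Two details matter on mixed-amplitude beat sequences:
the integrated envelope is square-root compressed before thresholding
(otherwise the squaring stage makes low-amplitude beat classes invisible
next to large ones), and missed-beat search-back re-examines any R-R gap
longer than 1.66 times the median at half threshold, iterated to a fixed
point and including the record edges. On annotated datasets the
annotations are always used instead; the detector exists for
unannotated data and is validated against the synthetic generator's
ground truth (recall and precision at least 0.95 at moderate noise).

## Dual-scale segmentation

Each labelled beat yields a *pair* of windows centred on the same
R-peak:

* **Fixed mode** (360 Hz layout): 143 samples left + R sample + 144
  right = 288 for the single-cycle window; 431 + 1 + 432 = 864 for the
  three-cycle window. The single-cycle window is by construction the
  central third of the three-cycle window. We read "143 left / 144
  right" as including the R sample in the left count — the only
  convention that makes the 288/864 totals exact.
* **Adaptive mode** (500 Hz layout): the per-record cycle length is
  $N_s = 60 / H_r \times S_r$ with the heart rate $H_r$ estimated from
  the median R-R interval (robust to detector slips; the estimator is
  ours to choose). Windows take $round(N_s/2)$ and $round(3 N_s/2)$
  samples on each side (round-half-up — "round" needs a tie rule and
  half-up keeps printed constants reproducible), then both are resized
  by cubic-convolution interpolation to 400 and 1200 samples. Whether
  the R sample belongs to a side count changes the pre-resize length by
  one; after resizing to a fixed target the distinction is immaterial,
  and we fix the left-count convention for definiteness.

Beats whose three-cycle window leaves the record are skipped (counted,
not errored) at both scales, so every sample is a complete pair.

The 1-D resampler is the standard Keys cubic-convolution kernel
($a = -0.5$) with endpoint alignment and clamped borders: constants are
reproduced exactly, integer-aligned resizes reduce to the identity, and
linear ramps are reproduced away from the borders. The same kernel,
applied separably, later resizes CNN feature maps during fusion.

## Time-frequency representation

Each segment becomes a magnitude short-time Fourier spectrogram using a
Kaiser window of 0.2 s with a 0.01 s hop:

$$w(n) = \frac{I_0\!\left(\pi\alpha\sqrt{1 - \left(\frac{2n}{N-1} - 1\right)^2}\right)}{I_0(\pi\alpha)},\qquad 0 \le n \le N-1 .$$

At 360 Hz this is a 72-sample window with hop $round(3.6) = 4$; at the
nominal 500 Hz of resized adaptive segments, 100 samples with hop 5.
With no zero padding the frame count is $\lfloor (L - N)/hop \rfloor + 1$,
which yields the four canonical shapes: 288 samples → 72 × 55,
864 → 72 × 199, 400 → 100 × 61, 1200 → 100 × 221. All $N$ DFT bins are
kept as rows — half are conjugate-redundant for real signals, but the
square-window geometry is part of the model contract (a `onesided`
option exists for diagnostics). The shape parameter defaults to
$\alpha = 3$, a moderate side-lobe/width trade-off; no downstream result
in this package depends on $\alpha$, and it is configurable. Magnitudes
are linear by default with a log option.

## Mixup oversampling

Minority classes are oversampled by Mixup: a convex combination of two
parents, $\tilde{x} = \varepsilon x_a + (1-\varepsilon) x_b$ and the same
combination of their one-hot labels, with
$\varepsilon \sim \mathrm{Beta}(1, 1)$, i.e. uniform. Mixing happens in
the time domain on the three-cycle signals; the mixed single-cycle
signal is the central cycle of the mixed three-cycle signal, so the
pair stays consistent (cropping is linear, hence the extracted window is
also the $\varepsilon$-mix of the parents' single-cycle windows).
Generation ratios are per class — by default 1, 0.5 and 2 for the S, V
and F families — and the generated count is $round(r_c\, n_c)$
(round-half-up, the rounding that reproduces the canonical
post-augmentation counts 4972 / 9689 / 2154 from training counts
2486 / 6459 / 718). Parents are drawn without replacement within a pair
and with replacement across pairs, seeded.

Per-class generated counts are only well defined when both parents share
the class, so mixing is intra-class by default and soft labels stay
one-hot; an `inter_class` flag exposes the general form, whose soft
labels the trainer accepts either way. Augmentation runs strictly after
the train/test split and only on the training side.

## The SE-multi-input CNN

Both spectrograms are z-scored per sample and enter parallel branches:

* Branch A (single-cycle): four 3 × 3 convolutions with 4, 8, 16, 32
  filters, stride 1, same padding, ReLU.
* Branch B (three-cycle): the same with 5 × 5 kernels.
* SE blocks after convolution layers 3 and 4 of each branch: global
  average pooling to one value per channel, a two-layer bottleneck
  (widths $C/2$ then $C$, i.e. 8/16 and 16/32 — ReLU then sigmoid), and
  channel-wise rescaling by the resulting gate in $(0,1)$. The gate can
  only attenuate, never amplify.
* Fusion: branch B's 32-channel feature maps are resized per channel to
  branch A's spatial size with the separable cubic kernel and the maps
  are summed element-wise; a per-channel instance normalization with
  trainable scale and shift follows ("feature normalization after
  fusion").
* Head: flatten (72 × 55 × 32 = 126 720 features for the 360 Hz layout,
  100 × 61 × 32 = 195 200 for the adaptive one), a 64-unit ReLU layer,
  and a softmax over 5 or 4 classes.

Listing only convolution/ReLU/SE stages and printed feature sizes leaves
stride and pooling open; we adopt stride 1, same padding and no pooling —
the minimal topology under which the fusion arithmetic is consistent.
The loss is cross-entropy against soft targets (required for Mixup
compatibility; one-hot labels are a special case). Training uses Adam,
default 30 epochs, batch 256, learning rate 0.001, with seeded
initialization (He) and shuffling, and global gradient-norm clipping at
5 to tame the first updates. All of it — convolution via im2col and BLAS
products, SE, instance norm, bicubic fusion, Adam — is implemented in
this package (R with C++ kernels); the gradient of every layer is
verified against central finite differences in the test suite.
Convolution arithmetic can run in float32 (`precision = "single"`,
about twice as fast, gradient error far below the stochastic-gradient
noise floor); the double-precision path is the default and the
reference the gradient checks run against.

`se_micnn()` is the single fitting entry point and returns a classed
object with `print`, `summary`, `predict`, `plot` and `coef` methods;
`branches = "single"|"three"` and `use_se = FALSE` give the ablation
variants that `ablation_report()` tabulates.

## The synthetic generator, and what it does not show

Every stage above is exercised end-to-end on synthetic records: beats
are sums of Gaussian bumps for the P, Q, R, S, T waves with per-class
amplitudes, widths and offsets; five default morphologies are shaped
after the AAMI families (e.g. the "V" class is wide, large, with a
discordant T wave; "Q" is low-amplitude). R-R intervals jitter
uniformly around the configured heart rate (default 75 bpm ± 8 %), and
three noise processes are added: a 0.3 Hz baseline sinusoid (0.15 mV), a
50 Hz powerline sinusoid (0.05 mV) and white noise (0.05 mV), all
configurable and all reproducible from one integer seed. Ground truth —
R-peak indices, labels, the clean trace — is retained, which gives the
denoiser, the detector and the classifier exact oracles.

The defaults are chosen so that the classes are *separable*: a
nearest-centroid rule on raw beats already exceeds 90 % accuracy. That
is deliberate — the generator's job is to certify that the pipeline can
learn and to expose regressions, not to emulate clinical difficulty.
Passing on this data shows the machinery is correct; it does not show
clinical-grade performance. Real ECG differs in ways the generator does
not model: morphology drifts within a patient, classes overlap, noise is
non-stationary and non-Gaussian, and electrode artefacts mimic beats.
Published headline accuracies on the real databases are therefore not
reproduced here; the package instead ships the full pipeline needed to
re-run them when the recordings are available locally (WFDB reading, the
MLII lead selection with record exclusions, annotation mapping).

## Problem sizes and numerical choices

The test suite trains networks at the true spectrogram geometry but on
small synthetic datasets; these sizes are package choices balancing
statistical meaning against the cost of CPU training:

* learnability benchmark: 5 records × 30 beats (120 training beats,
  balanced five classes, 20 % held out), 72 × 55 / 72 × 199 inputs,
  Adam at 3 × 10⁻⁴, batch 8, 7 epochs — small batches give a small
  dataset more updates per epoch, and a learning rate below the
  real-data default keeps the first epochs stable on tiny batch
  statistics.
* SE-vs-no-SE comparison: 600 fresh synthetic beats seen exactly once
  (single-pass training cannot overfit, so both variants approach their
  asymptote), 75 held-out beats, one-sided spectrograms (redundant
  conjugate rows dropped), ten seeded repetitions of both variants.
  Variants are *paired*: SE parameters are always drawn during
  initialization and simply dropped for the no-SE model, so the common
  layers start from identical weights under one seed and the comparison
  isolates the SE contribution. Direction, not magnitude, is the claim
  under test — and at this problem size it should be read with care:
  with a few hundred separable training beats the SE blocks add
  optimization variance without a measurable accuracy gain, so SE and
  no-SE variants finish statistically tied; the published advantage of
  channel attention is a property of training corpora orders of
  magnitude larger.
* capacity check: a single record overfit to 100 % training accuracy.

Other numerics: round-half-up wherever a printed integer depends on a
tie (documented above); zero-denominator metrics report 0 with a flag
rather than NaN; percentages are kept at full precision internally and
rounded only for display; the epsilon in instance normalization is
10⁻⁵; softmax is computed with the max-subtraction trick; WFDB signals
are digitised at a configurable ADC gain (default 200 adu/mV, format
212 clipping at ±2048) so round-trips are exact to half a quantization
step.

## Evaluation

`confusion_matrix()` + `per_class_metrics()` implement the one-vs-rest
metric suite as percentages:
$Acc = (TP+TN)/(TP+TN+FP+FN)$, $Sen = TP/(TP+FN)$, $PPV = TP/(TP+FP)$,
$F1$ the harmonic mean of the last two, and macro scores as unweighted
arithmetic means over classes — per-class accuracy is one-vs-rest (its
TN counts all correct non-class outcomes), which is the reading under
which a per-class accuracy table is well defined. The implementation is
tested against a brute-force recount from raw label vectors.

## Known limitations

* The CNN trains on CPU in R; it is meant for the small-to-moderate
  studies this package targets, not for training on the full 96 k-beat
  corpus (a full-scale run is hours, not minutes).
* The WFDB reader covers headers, formats 212/16 and beat annotations —
  enough for the MIT-BIH layout — not the full format zoo.
* The detector is tuned for single-lead beat trains; it is not a
  general-purpose clinical QRS detector.
* Inter-class Mixup produces genuinely soft labels; evaluation
  currently hardens predictions by arg-max only.
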
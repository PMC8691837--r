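---
title: "Simulated ghost cytometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated ghost cytometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostflow)
```

## The measurement model

Ghost motion imaging (GMI) is a compressive imaging scheme: a cell flows
at constant speed through a *static* structured illumination pattern and
a single-pixel detector records the total transmitted (or scattered)
light over time. Writing the projected cell image as a matrix $I$
(`h x w` pixels, flow axis first) and the binary illumination mask as
$H$ (`F x W`), the detector signal at sample $t$ is

$$ G(t) \;=\; g \sum_{r,j} H[t-h+r,\, j]\; I[r, j] \;+\; b , $$

a discrete cross-correlation of the mask with the moving image, summed
over the lateral axis. One temporal waveform of $F + h - 1$ samples
therefore encodes a compressed random projection of the full 2D image —
far more morphological information than the single scalar a conventional
forward-scatter (FSC) or side-scatter (SSC) detector yields, while
remaining acquirable at flow-cytometer rates. `ghostflow` implements
this forward model (`gmi_waveform()`), the surrounding instrument
(phantoms, noise, triggering, segmentation), and the downstream
in-silico-labeling analysis: classifiers that predict a cell's
fluorescence label from its stain-free waveforms, and an in-silico
sorter driven by those predictions.

Five modality names are supported — `dGMI` (diffracted), `ssGMI`/`bsGMI`
(side/back scatter), `fsGMI` (forward scatter) and `bfGMI` (bright
field). They share the same mathematics and differ only in which phantom
contrast map they read (`transmission`, `scatter`, or `absorption`) and
in their independent illumination masks.

The discretization is exact by construction: the default sampling period
equals `pitch / flow_speed`, i.e. one pixel of object translation per
sample, so the waveform is a pure discrete correlation with an exact
brute-force oracle. Entry and exit are zero-padded (the full traversal
is recorded). These two choices make the forward model testable to
numerical precision, which the test suite and the reconstruction module
exploit.

## Phantoms: what the generator emulates

Real cells are replaced by 2D projected phantoms on a 64 x 32 pixel
canvas at 0.5 um/pixel (so a 128-row default pattern gives raw waveforms
of 191 samples and extracted segments of 128 — comfortably over 100
points per waveform). A phantom is an elliptical support (major axis
along the flow) with:

* `diameter` (um) — sets the support size; FSC pulse area scales with
  it.
* `nucleus_fraction` — an inner, 1.8x denser ellipse occupying that
  fraction of the projected area.
* `granularity` — the amplitude of mean-one multiplicative lognormal
  speckle (sdlog 0.7). Texture amplitude scales with granularity while
  the *expected* total intensity does not, so granularity is visible in
  waveform fluctuation structure but nearly invisible to integrating
  scalar detectors. This is the central design device: it reproduces,
  on synthetic data, the situation where two populations overlap in
  FSC/SSC but differ in image content.
* `eccentricity`, `membrane_irregularity` — elongation and low-order
  angular perturbation of the membrane radius (blebbing).
* `optical_density` — overall contrast scale.

Viability states are encoded by standard cytological correlates
(`viability_spec()`): apoptotic cells shrink, bleb and roughen; dead
cells lose optical density and become highly granular. These are
modeling conventions, not measured biology.

What the phantoms do **not** model: wave-optical speckle formation,
diffraction, 3D structure, refractive-index distributions, organelles,
or any physically calibrated transfer function. Passing tests on this
generator demonstrate that the *pipeline* recovers information the
forward model provably encodes; they do not certify performance on real
instrument data.

Per-event randomness flows through a counter-based scheme: event $i$ of
a population with seed $s$ draws its class, morphology jitter (truncated
normal at +/- 2.5 sd, which also keeps phantoms on-canvas) and texture
from seeds derived from $(s, i)$, so streams are bitwise reproducible
and any subset of events can be regenerated independently.

## Noise and the photon budget

Detector noise is scaled-Poisson shot noise plus Gaussian read noise:
`Poisson(shot_scale * x) / shot_scale + N(0, read_sigma)`. The default
`shot_scale = 10`, `read_sigma = 0.5` corresponds to roughly ten
detected photons per intensity unit; at typical mask overlap intensities
(~150 units) the per-sample SNR is ~40. This budget was fixed while
designing the generator so that the texture-variance signal the
benchmark is built around is physically present in the waveforms: at a
tenfold lower budget, shot noise (variance `x / shot_scale`) swamps the
texture-induced fluctuation variance and no classifier — of any family —
could recover the class difference, which would contradict the premise
the benchmark encodes. Batch effects can scale the noise floor per
donor (`batch_effect(noise_scale = ...)`).

## Signal chain

The acquisition emulates a digitizer: every channel passes a single-pole
recursive high-pass (`y[t] = alpha (y[t-1] + x[t] - x[t-1])`,
`alpha = 0.995`, initialized so a constant input maps to exactly zero —
an analytically testable AC coupling); a trigger fires at the first run
of `trigger_min_run = 3` samples strictly above `trigger_threshold = 3`
on the FSC channel; and a fixed window of `segment_length = 128` samples
starting `pre_trigger = 8` samples before the trigger is cut from
*every* channel, so modalities stay time-aligned. Phantoms that never
meet the trigger condition are counted as dropouts, never silently
discarded. Pulse height/width/area come from the FSC segment (width at
half height by default), which is what separates doublets from singlets.
Segment length, pre-trigger and the filter pole are declared,
configurable defaults: the underlying hardware quantities are outside
the model.

## Supervision, gating and splits

Fluorescence supervision is a strict threshold (`intensity > t` is
positive; equality is negative — a stated convention, as is "polygon
boundary counts as inside"). Gates operate on raw linear scalar values;
logarithmic display is a rendering choice the package does not bake into
geometry. Hierarchical schemes apply an ordered list of keep/assign
rectangle (or polygon) gates, first assignment wins, and class counts
plus "ungated" conserve the total exactly. Balanced splits draw exact
per-class train/test sets without replacement (the repeated
random-sampling protocol); `fraction_split()` provides stratified 70/30
style splits.

## The SVM stack

Features are the concatenated waveform segments and/or scalars,
standardized per feature by a normalizer fitted **on the training split
only** (a leakage test asserts this code path). Hyperparameters are
chosen by inner stratified 5-fold cross-validated AUC over
`C in 10^{-2..3}` (and `gamma in 10^{-4..1}` for the RBF kernel), ties
broken toward smaller `C` then smaller `gamma`; the final model refits
on the full training split. AUC is computed by threshold sweep with
trapezoid integration, which equals the Mann-Whitney
probability-of-correct-ranking with ties counted one half — an identity
the tests verify against an independent pairwise oracle.

`repeated_eval()` runs ten independent balanced samplings and reports
*both* the mean +/- sd of per-trial AUCs and the AUC of the vertically
averaged mean ROC (101-point uniform FPR grid, linear interpolation):
the two summaries differ slightly and are deliberately kept distinct.
`recovery_at_fpr()` reads the TPR off a (mean) ROC at a fixed
false-positive budget. `simulate_sort()` keeps events whose decision
score exceeds a threshold (default 0, the decision boundary) and reports
pre-/post-sort target fractions and yield. For linear kernels,
`export_linear_scorer()` folds the normalizer into a raw-space weight
vector and bias whose dot-product scores match `svm_score()` to 1e-9 —
the form a real-time (e.g. FPGA-hosted) scorer would deploy; kernelized
models are refused rather than approximated.

The shipped two-class benchmark (`benchmark_two_class_spec()`) uses the
RBF kernel with a compact grid (C in {1, 10, 100}, gamma in {1e-3, 1e-2,
1e-1}). The choice is forced by the geometry of the problem: the
benchmark classes are mean-matched by design, so the discriminative
signal is the *variance* structure of the waveform, which no linear
decision function can express (measured: linear AUC 0.50, RBF 0.96 on
identical data). The compact grid brackets the selected values and keeps
a ten-trial evaluation at desk scale; the full default grids remain
available through `svm_config()`.

## The convolutional classifier

The six-class network follows a fixed recipe: five convolutional blocks
(kernel 5, channels 16/32/64/64/64, each block = convolution -> batch
normalization -> ReLU -> max-pool 2) over the stacked waveform channels
(`dGMI`, `bsGMI`, `fsGMI`, `bfGMI` by default), a single fully connected
layer (width 64), and a softmax layer; categorical cross-entropy; Adam;
early stopping that restores the best-validation-loss weights after 30
stagnant epochs (500 epoch ceiling). A 128-sample segment enters the
flatten stage as 4 temporal positions x 64 channels. All forward and
backward passes are implemented in-package on BLAS matrix
multiplications; training is exactly reproducible given the seed on a
fixed BLAS configuration (single-threaded execution; across BLAS builds
a tolerance of +/- 0.01 macro-F1 is the declared expectation).

Two choices were genuinely open:

* **Where scalars join.** "Concatenated at the fully connected stage"
  admits two readings; the default concatenates FSC/BSC scalars to the
  *flattened convolutional output entering* the FC layer, because only
  then can the FC layer mix scalar and waveform information before the
  softmax. The alternative (concatenation to the FC *output*) is
  available as `scalar_concat = "after_fc"`.
* **Learning rate at desk scale.** The recipe's nominal values (Adam at
  1e-5, batch 1024, 500 epochs) suit populations of tens of thousands
  of cells, i.e. >= 10^4 optimizer steps. With a few hundred
  training events and the desk-scale batch rule
  `batch = min(1024, n/4)`, 500 epochs supply only ~2000 steps, bounding
  each weight's total movement near 2e-2 — the network provably cannot
  leave its initialization basin (measured macro-F1 0.54 at 1e-5 vs 0.96
  at 1e-3 on the same population). The package therefore defaults to
  `learning_rate = 1e-3`; the original value is one configuration field
  away.

Per-layer channel counts, kernel and pool sizes are fixed defaults of
this package; the underlying recipe does not specify them.

Evaluation is 10-fold stratified cross-validation (the held-out fold
doubles as the early-stopping validation set), reporting mean +/- sd of
per-fold macro-F1 (unweighted mean of per-class F1, F1 = 0 for a class
with zero precision and recall) and the best fold's confusion matrix.
`transfer_eval()` contrasts within-batch 70/30 performance against
training on one donor batch and testing on another.

## Reconstruction as a validation oracle

`sensing_matrix()` stacks the forward model of several independent
patterns into one linear operator `A`, so `A vec(I)` equals the
concatenated waveforms exactly; `reconstruct_image()` inverts it by
dense QR least squares (optional Tikhonov ridge; rank deficiency at
ridge 0 is an error advising regularization, not a silent minimum-norm
answer). With at least as many measurement rows as pixels, noise-free
recovery of random objects is exact to 1e-6 relative error. The module
exists to *certify* that the compressive waveforms carry full image
information; the classification pipeline itself never reconstructs
images — that reduced acquisition is the point of the method. The
static-object formulation (one object, many patterns) suffices for this
certification; streaming multi-cell reconstruction is out of scope, and
objects are capped at 64 x 64.

## Persistence and interoperability

Event tables round-trip through a versioned RDS container carrying a
provenance block (configuration hash, seeds, package and R versions);
reads verify the schema version and the cross-group event-count
invariant. Scalar channels export to FCS 3.1 (32-bit little-endian
floats, channels FSC-H/W/A, SSC, BSC plus fluorescence) for
conventional cytometry software; the writer is implemented in-package
and its output is verified in the tests by an independent parser that
trusts only the written header offsets. Configurations are YAML with a
closed set of sections — unknown keys are rejected rather than ignored.

## Problem sizes used by the shipped evaluations

The packaged benchmarks run at desk scale by design: the two-class
benchmark uses 1000 events per class with ten random samplings of 300
train + 300 test per class; the six-class population uses 600 events
(rare class ~6%) under 10-fold cross-validation with a 150-epoch
training ceiling (early stopping selects epochs in the 30-80 range, so
the ceiling is slack, but it bounds the pathological case where a small
validation fold resets the patience counter with hairline
improvements); reconstruction certification uses objects up to 16 x 16.
These sizes are the package's declared study conditions; all thresholds
quoted in the tests were fixed together with them.

## Known limitations

* Phantom optics are schematic; absolute AUC/F1 values characterize the
  synthetic populations, not any instrument or biological sample.
* The Bernoulli mask statistics and all transfer functions are declared
  stand-ins; real structured illumination patterns are shaped by the
  optics that produce them.
* Scalar SSC/BSC are modeled as noisy totals of the scatter map; angular
  scattering physics (which makes real SSC granularity-sensitive in
  *mean*, not only variance) is not modeled.
* The CNN is CPU-oriented and small; no architecture search was
  performed, and its hyperparameters beyond the recipe are fixed
  defaults.
* Hardware-level concerns — fixed-point quantization of the exported
  linear scorer, trigger re-arm dead time, analog electronics — are out
  of scope.
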
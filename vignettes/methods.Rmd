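---
title: "Methods: attention-guided region discovery and fusion regression for bone age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-guided region discovery and fusion regression for bone age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bone age assessment (BAA) estimates skeletal maturity in months from a
hand/wrist radiograph. Clinical practice concentrates on a small number of
anatomically informative regions — above all the carpal bones and the
metacarpus & phalanx bones — but deep-learning pipelines either consume the
whole radiograph (discarding that prior) or rely on manually annotated
bounding boxes (expensive, subjective). `osteoage` implements a two-stage
alternative that needs no region annotation at all:

1. **Critical-region discovery.** A convolutional age regressor augmented
   with a convolutional block attention module (CBAM) is interrogated with
   Grad-CAM. The peak attention area of the heat map is taken as the first
   critical region (empirically the carpal area), cropped, and masked with
   a black rectangle; re-running saliency on the masked image moves the
   peak to the second region (metacarpus & phalanx). This crop-then-mask
   loop is the cascade.
2. **Fusion age regression.** Two branch CNNs embed the two crops; the
   branch features are exchanged as a whole and concatenated so each path
   sees both regions; an encoded gender covariate is fused through
   learnable scalar weights, `x~ = alpha_D * x_D + alpha_G * x_G`; a fully
   connected head outputs age in months. Training minimizes mean squared
   error; the reported metric is mean absolute error (MAE), the field's
   standard.

## The attention and saliency machinery

Channel attention computes one sigmoid weight per channel,
`sigma(MLP(AvgPool(F)) + MLP(MaxPool(F)))`, with a shared two-layer MLP
applied to the globally average- and max-pooled channel descriptors.
Spatial attention pools the refined volume across channels into a
two-channel (mean, max) map, convolves with a single 7x7 kernel (zero
padding 3, so shape is preserved) and applies a sigmoid. The module
multiplies the input by the channel weights, then the result by the
spatial weights.

Two details are deliberately configurable because the published
description leaves them open:

* **Reduction ratio `r`** of the shared MLP defaults to 16 (standard CBAM
  practice); any divisor of the channel count is accepted, and an identity
  MLP (`r = 1`, identity weights, no hidden ReLU) is constructible so
  closed-form test cases exist.
* **Hidden nonlinearity and biases.** The weight-only composition
  `W1(W0(s))` is the documented form; a ReLU between the two maps is
  standard in CBAM implementations and is on by default (`mlp_relu`),
  biases are off by default (`mlp_bias`). Test fixtures use the identity
  MLP to sidestep both.

Grad-CAM differentiates the scalar regression output (no class selection
exists) with respect to a chosen convolutional layer's activations,
averages the gradient spatially per channel, forms the rectified weighted
channel sum, upsamples bilinearly to the image grid, and normalizes the
peak to exactly 1 — an identically zero raw map stays zero and is reported
to the cascade as "no salient region". The default source layer is the
last spatial layer; any spatial layer can be named. Because no automatic
differentiation framework is available in this R environment, the package
carries its own small CNN engine (convolution via im2col in C++, pooling,
dense, CBAM and log layers) with closed-form backward passes; every layer
is validated against central finite differences in the test suite, which
is also exactly the machinery Grad-CAM needs.

## Turning a heat map into a box

The published method says only that the *peak attention area* is cropped.
The package's reading, fully parameterized: take the global maximum pixel
(ties broken to the first in row-major order), grow the 8-connected
component of pixels at or above `threshold_frac` (default 0.5) times the
maximum, take its bounding box, pad each side by `pad_frac` (default
0.10) of its length, clip to the image, and enforce a minimum side length
(default 32 px at the 300 px working scale, scaled proportionally for
smaller images). Masking fills the box with exact zeros ("black
rectangle"); later boxes are clipped against earlier ones so box
interiors are always pairwise disjoint — overlap behavior is unstated in
the source and disjointness is the only ordering-independent convention.
All coordinates are 0-based and half-open, and every serialized record
carries that convention string. Role labels follow discovery order
(carpal first, metacarpus & phalanx second), mirroring the clinically
observed attention order, and can be overridden since the order is
model-dependent.

Two crop operators exist: `crop_region()` resamples the box to a target
size (bilinear, half-pixel centers) — appropriate for anatomy, whose shape
survives rescaling; `crop_fixed()` takes a fixed-size window centered on
the box at native scale. The synthetic experiments use `crop_fixed`,
because their age signal is texture *grain size*, which per-box rescaling
would corrupt with magnification noise.

## The fusion regressor

Branch backbones are registered by name. `small_cnn` (three convolution
blocks, 8/16/`feature_dim` channels, optional CBAM block after the first
stage, global average pooling) and `small_cnn_wide` are bundled and
trainable on one CPU; `xception` and `resnet50` are registered as names
for third-party implementations and error informatively when constructed,
since no R package in the environment provides them. After global
pooling, features pass through a **log-energy readout** (`log(x + 1e-6)`)
— texture grain is carried by energy *ratios* across scales and filters,
and the log turns ratios into linear combinations, which is also why
log-energy readouts are standard in texture discrimination.

The exchange contract: branch A's downstream path receives
`c(feat_B, feat_A)`, branch B's receives `c(feat_A, feat_B)` — the
vectors are swapped as wholes and concatenated, so the swap is an
involution. Each path is projected (linear + ReLU, width `p_dim = 32`),
the two paths concatenate into `x_D`, and the gender pathway — a linear
embedding of the binary male flag into `d_g = 32` dimensions, projected
to `x_D`'s dimension — joins through `alpha_D * x_D + alpha_G * x_G` with
both alphas scalar and learnable. The source describes per-layer weights
`alpha^l`; the architecture diagram shows a single fusion site
(pre-head), so one pair of scalars is implemented. Setting
`use_gender = FALSE` removes the pathway entirely and `use_cbam = FALSE`
removes the CBAM blocks, reproducing the four ablation arms structurally.

## Training

Targets are standardized internally (train-fold mean/sd); minibatch Adam
minimizes MSE; per-epoch train/validation MSE and MAE are logged in
months. Defaults follow the reference settings — learning rate 3e-4, 30
epochs, 300x300 working resolution — with batch size 16 and Adam as
package choices where the source names none. Data splits are 80/10/10 by
seeded shuffle; the same split serves both stages. `fit_bone_age()`
returns the parameters of the epoch with the lowest validation MAE
(standard guard against late-epoch optimization noise; the full history
is kept). Augmentation — resize jitter, rotation within ±15°, contrast
0.8–1.2 about the image mean, brightness ±10%, in that order, each drawn
from a per-sample seeded stream — is available but off by default: at the
desk-scale problem sizes below it slows convergence more than it helps
generalization.

## What the synthetic generator emulates — and what it does not

Real radiographs encode maturity through ossification detail in specific
regions. The generator reproduces exactly that statistical structure at
desk scale (64x64 by default): a smooth hand silhouette (soft palm and
finger lobes) that carries *no* age information, plus two planted
textured discs — a carpal-like disc (radius 13 px, amplitude 0.30) and a
metacarpus-like disc (radius 12 px, amplitude 0.20) with jittered
centers. Inside the discs, texture grain sigma falls exponentially from
2.0 px to 0.4 px and the disc edge transition narrows from 2.5 px to 0.5
px as latent age runs over 12–216 months (the pediatric range of the
public RSNA cohort), so age is encoded in *texture scale and edge
sharpness, never in mean intensity* — localization cannot shortcut
through global brightness. Disc profiles have compact support (cosine
ramp), so pixels outside the discs are provably age-free; texture noise
is clipped at ±2 sd so intensity clamping cannot erode the variance
contrast between the discs; and intensities are floored at 0.02 so exact
zero remains unambiguous as the black-mask sentinel.

The observed label is `latent + 6 * male + N(0, 2)` months. Gender is
assigned **age-matched**: consecutive samples form male/female pairs
sharing one latent age. In a finite cohort of 500, independently drawn
genders can produce several months of spurious age–gender imbalance that
would confound a ±6 month effect; the matched design identifies the
effect, as a matched clinical study would.

The toy saliency model used to exercise the cascade without training is
analytic: a local-variance map (window 5), gated to ignore windows
touching exact zeros (so freshly masked rectangles are invalid rather
than high-contrast edges), box-smoothed with a 15 px kernel — emulating
the low spatial resolution of real CNN saliency maps, so the peak
attention area is a blob over the whole textured region — and globally
averaged into a scalar texture-energy score. Its Grad-CAM heat map is
provably proportional to the smoothed variance map.

What the generator does *not* emulate: anatomy (no growth plates, no
bones), intensity calibration differences between scanners, hand pose
variation, or any spatial correlation between regions. Passing the
synthetic end-to-end checks therefore demonstrates that the pipeline's
machinery — saliency, cascade, fusion, gender use — functions and
recovers planted signal; it says nothing about clinical accuracy on real
radiographs.

## Problem sizes and numerical choices

The packaged experiments use: 50 images for cascade recovery; 500 samples
(80/10/10) at 64x64 with 32x32 fixed-scale crops, 40 epochs of Adam at
learning rate 2e-3, batch 16, for the end-to-end and gender comparisons;
160 samples and 6 epochs per arm for the structural ablation table. The
gender-ablation *direction* (with-gender beats without-gender) is scored
on a 300-sample independently simulated evaluation cohort rather than the
50-sample test fold: a fold of 50 estimates MAE with roughly ±0.6 months
of noise, the same order as the generalization gap a ±3-month gender
offset leaves once the texture signal is well fitted, and simulation
affords an evaluation cohort large enough to measure that gap rather than
the fold noise. The 50%-of-baseline margin and the containment check,
whose margins are large, stay on the standard test fold. These
sizes were chosen so the full suite trains several models comfortably on
a single CPU while leaving clear margins: the trained model's held-out
MAE (typically 6–9 months) sits far below the constant predictor
(~45–50 months), and masking both planted regions collapses performance
back to that baseline.

Numerical conventions worth knowing: convolutions are cross-correlations,
stride 1, zero padding; max pooling breaks ties to the first element in
column-major order, making all passes bit-deterministic; bilinear
resampling uses half-pixel-center alignment; heat maps normalize by their
maximum with the all-zero case defined as all-zero; Adam uses
beta = (0.9, 0.999), eps = 1e-8. Checkpoints are single RDS files
embedding a JSON config block (model class, backbones, dimensions, flags,
coordinate convention, package version).

## Known limitations

* Backbone scale: the bundled backbones are deliberately small; nothing
  prevents plugging larger ones into the registry, but ImageNet-scale
  pretraining is out of scope.
* The cascade's box rule is one faithful reading of "peak attention
  area"; other readings (e.g. fixed-fraction crops around the argmax) are
  possible and would need only `locate_peak_region` to change.
* Single-site gender fusion: if the per-layer reading of the fusion
  weights is preferred, the fusion would need to be replicated at several
  depths; the implemented reading matches the published architecture
  diagram.
* Training is sequential (no batching across samples inside the linear
  algebra), which is fine at desk scale but not for full-resolution
  cohorts.
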
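---
title: "Adversarial wound segmentation and morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial wound segmentation and morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(woundseg)
```

woundseg segments skin wounds from RGB photographs with a conditional
generative adversarial network and then measures the segmented regions:
dimensions, three shape descriptors, and an approximate shape call meant to
suggest a dressing shape. This vignette explains the models, the choices
behind them, and what the package's synthetic test bed does and does not
demonstrate.

## The segmentation model

The generator $G$ is a U-Net: an encoder of stride-2 $4\times4$
convolutions (leaky ReLU, slope 0.2; batch normalization on all levels but
the first) that halves the resolution per level, and a mirrored decoder of
stride-2 $4\times4$ transposed convolutions (ReLU; batch normalization on
all levels but the last) that doubles it, each decoder level concatenating
the same-resolution encoder activation. The final level maps to a single
channel through a sigmoid, so $G(x) \in [0,1]^{H\times W}$ is a per-pixel
wound probability. Filter counts follow
$\min(\text{base} \cdot 2^{\min(i-1,\,3)}, 512)$; depth, base width and the
number of innermost decoder levels with dropout (rate 0.5) are
configurable, with defaults depth 6, base 64, dropout on 3 levels at the
256 px working resolution.

The discriminator $D$ scores *patches* rather than the whole image: the
photograph and a mask (target $y$ or generated $G(x)$) are concatenated
channel-wise (4 channels) and passed through six stacks of $4\times4$
convolutions with filters $(64,128,256,512,512,1)$ and strides
$(2,2,2,2,1,1)$; stacks 1–5 use batch normalization and a leaky ReLU,
stack 6 a sigmoid. With same-style padding a 256 px input yields a
$16\times16$ matrix of patch scores; its mean is the scalar "patch-out".
Patch-level supervision gives the generator spatially fine-grained
feedback, which is what makes the adversarial term useful for boundary
quality.

## Losses and training

With patch scores clamped to $[\varepsilon, 1-\varepsilon]$
($\varepsilon = 10^{-7}$), the discriminator minimizes the scaled
adversarial loss

$$L_{discr} = \alpha\,\bigl(-\mathbb{E}\log D(x,y) -
\mathbb{E}\log(1 - D(x, G(x)))\bigr), \qquad \alpha = 0.5,$$

and the generator the compound loss

$$L_{gen} = \lambda_1\, L_{adv} + \lambda_2\, L_{rec}, \qquad
\lambda_1 = 1,\ \lambda_2 = 100,$$

where $L_{rec}$ is the pixelwise absolute difference between $y$ and
$G(x)$ and $L_{adv}$ defaults to the non-saturating surrogate
$-\mathbb{E}\log D(x, G(x))$ (the saturating minimax form
$\mathbb{E}\log(1-D(x,G(x)))$ is available behind the `saturating` flag,
but its gradient vanishes exactly where an untrained generator starts, and
stable training practically requires the surrogate). Two deliberate
normalization choices:

* **Reconstruction normalization.** The absolute-difference loss is
  written as an unnormalized pixel sum in the original formulation; at
  $256^2$ pixels a summed $L_{rec}$ with $\lambda_2 = 100$ would dominate
  the adversarial term by six orders of magnitude and reduce training to
  plain L1 regression. The default is therefore the mean
  (sum divided by the pixel count $n$), which preserves the intended
  $\lambda_1 : \lambda_2$ balance at any resolution; `reconstruction_mode
  = "sum"` restores the literal sum.
* **Adversarial expectations** are estimated as means over all patches of
  all batch samples, consistent with patch-level supervision.

Training alternates exactly as in the classic conditional-GAN recipe: per
step, sample a minibatch, generate $G(x)$, update $D$ on the real and fake
batches under $L_{discr}$, then update $G$ against the just-updated $D$
under $L_{gen}$. Both networks use Adam with $\eta = 0.002$,
$\beta_1 = 0.5$ (the customary reading when a single $\beta$ is quoted for
GAN training), $\beta_2 = 0.999$; the default batch size is 16. "Best
model" selection is operationalized deterministically: a fixed held-out
batch (seeded draw from the training set) is scored with $L_{gen}$ after
every step and the generator achieving the minimum is checkpointed. All
randomness — initialization, shuffling, dropout, data synthesis — is
governed by explicit seeds, so runs replay bit-identically.

The layers themselves (convolution and transposed convolution via
im2col/GEMM, batch normalization, dropout, Adam, and full backpropagation)
are implemented in the package (R with RcppArmadillo kernels); gradients
of every layer and of both assembled networks are verified against central
finite differences in the test suite, and a wiring test checks that a
single adversarial gradient step strictly decreases the generator's
adversarial term.

## Morphological feature estimation

Predicted probability maps are thresholded at 0.5 (ties counted as wound)
and post-processed:

1. **Noise removal** by opening-by-reconstruction with a disk of radius 2:
   components that vanish under the plain opening are dropped, survivors
   are kept pixel-exact. A plain opening was rejected because it clips the
   corners of rectangular regions and shaves the four extreme pixels off
   small digital disks — measured on a radius-10 disk this inflates
   rectangularity from 0.72 to 0.87 and flips the shape call.
2. **Hole filling** (background components unreachable from the border),
   so area and perimeter describe the filled wound bed.
3. **Area floor**: components below `min_area` (default 0.05% of the
   image) are removed. The pipeline is idempotent.

Connected components (8-connectivity by default, 4 available) become wound
regions, ordered by decreasing area. Per region the package measures the
pixel-count area $A$; the perimeter $r$ as the closed outer-contour arc
length from Moore-neighbor tracing, with unit steps for 4-neighbor moves
and $\sqrt2$ for diagonals (this estimator is fixed so that descriptor
tolerances are reproducible; it overestimates smooth-curve length by a few
percent, which the stated tolerances absorb); the axis-aligned bounding
box (width = column extent, length = row extent); and the
moment-equivalent ellipse axes from central second moments. Isolated
single pixels get perimeter 1 by convention; they cannot survive cleanup
with default parameters.

The three shape descriptors are

$$e = \frac{\sqrt{\text{major}^2 - \text{minor}^2}}{\text{major}}, \qquad
\Omega_c = \frac{A}{r^2}, \qquad
\psi_R = \frac{A}{\text{width}\times\text{length}}.$$

Here "foci over major axis" is read as the inter-focal distance over the
major-axis length — the standard ellipse eccentricity, and the only
reading consistent with $0 \le e \le 1$. $\Omega_c$ is taken literally as
$A/r^2$ (so a disk attains $1/(4\pi) \approx 0.0796$, not 1). The
"boundary box" of $\psi_R$ is the axis-aligned bounding box; a rotated
minimum-area box would be plausible but is not what the rest of the
measurement pipeline (width/length reporting) uses.

**Shape call.** The source formulation computes all three descriptors but
never states a decision rule, so the rule here is the package's own:
rectangle if $\psi_R \ge 0.85$, else circle if $e \le 0.40$, else ellipse.
The thresholds sit at wide margins from the ideal values
($\psi_R = 1$ for an aligned rectangle vs $\pi/4 \approx 0.785$ for any
ellipse; $e = 0$ for a circle vs $e \ge 0.6$ for the 0.45–0.8 axis ratios
the synthetic generator draws). $\Omega_c$ is reported in the measurement
table but deliberately unused by the default rule, which keeps the rule
non-redundant; both thresholds are configuration keys. Per shape call the
displayed dimensions are: circle — equivalent diameter $2\sqrt{A/\pi}$;
ellipse — moment-equivalent major/minor axes; rectangle — bounding-box
width and length; all with area and perimeter. Overlays draw region
boundaries green, yellow, blue by area rank; numeric annotations live in
the measurement table rather than rendered text.

## The synthetic test bed

Real wound photograph datasets cannot ship with the package, so a seeded
generator renders scenes that emulate their *task structure*: a noisy
skin-toned background (base RGB (0.72, 0.55, 0.45), per-scene tone jitter,
iid Gaussian texture, sd 0.02) containing 1–3 non-overlapping reddish
regions (base RGB (0.92, 0.15, 0.18)) whose exact rasterizations are the
ground-truth masks. Shapes are disks, ellipses or axis-aligned rounded
rectangles, kinds sampled uniformly, extents uniform in 10–30% of the
image side, ellipse axis ratios in 0.45–0.8, corner radii in 10–25% of the
shorter side; outlines can be perturbed by a smooth low-frequency radial
jitter (harmonics 2–4, default amplitude 3% of size) because real wounds
are not perfect conics and the measurement stage must tolerate that.
Scenes guarantee a 2 px image margin and ≥ 3 px pairwise separation, so
component labeling provably recovers the planted shape count. The colors
guarantee the documented invariant that the mean red channel inside the
wound exceeds the outside — the learnable cue.

What passing tests on this bed shows: that the optimization machinery,
losses, metrics and morphometry are wired correctly, and that the network
can learn a color/texture segmentation cue end to end. What it does not
show: performance on clinical images, which vary in illumination, skin
pigmentation, wound tissue composition, specularities and occlusions none
of which are modeled here. Headline overlap scores from any clinical
benchmark are therefore out of scope for the test suite; notably, a
reported IoU *larger* than Dice cannot arise from the confusion-count
definitions (always $\mathrm{IoU} \le \mathrm{Dice}$, since
$\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$), so such printed pairs
cannot be reproduction targets even in principle.

## Problem sizes and numerical choices

The test suite and the acceptance script run on one CPU and choose sizes
accordingly, as the package's own study conditions:

* The augmentation-count check runs 1010 synthetic scenes at 64 px
  (~0.5 GB for the resulting 4040 pairs; the count contract is
  resolution-independent). The default policy keeps each original plus 3
  variants, each variant applying exactly one technique drawn without
  replacement from {brightness, saturation, right-angle rotation,
  horizontal flip, vertical flip} — matching the published 4× growth while
  keeping the composition configurable. Right-angle rotations and flips
  are exact array permutations, so masks stay binary and incur no border
  fill; photometric factors default to U(0.8, 1.2).
* The overfit sanity run trains on 8 scenes at 64 px with a depth-4,
  base-16 generator, a (16,32,64,64,64,1) discriminator, batch 4, 300
  steps, seed 7, and requires mean training-set Dice ≥ 0.80 after
  thresholding. Dropout is disabled for this fixture: the check verifies
  that the adversarial optimization can memorize a tiny set, and dropout
  is a regularizer built to prevent exactly that. The run reaches Dice
  1.0 in about two minutes.
* The shape-call suite uses 200 jitter-free scenes at 128 px with extents
  18–35% of the side, so every shape is ≥ 20 px across — the regime where
  rasterized descriptors are within their stated tolerances of the
  continuous values (circularity within 10%, equivalent diameter within
  2%, eccentricity ±0.03).

Other numerical choices: log arguments clamped at $10^{-7}$ (prevents
$-\infty$ at sigmoid saturation; clamped scores get zero gradient);
binarization ties won by the wound class; batch normalization uses batch
statistics in training and running averages (momentum 0.1) in evaluation,
falling back to batch statistics before any training step; Adam
$\epsilon = 10^{-8}$; weights initialized $N(0, 0.02)$. Degenerate metric
denominators follow segmentation-benchmark practice: two empty masks
compare as perfect agreement (all metrics 1), any other 0/0 as 0, each
with a logged warning. Eccentricity of a degenerate one-pixel-wide region
is 1; a single-pixel region reports $e = 0$.

## Known limitations

* No photorealism: no hair, shadows, specular highlights, multi-tissue
  wound beds, or camera color casts; no color-constancy correction.
* Measurements default to pixels; physical units require the caller's
  `mm_per_px` scale (no camera calibration).
* The perimeter estimator's systematic few-percent overestimate on smooth
  boundaries propagates into circularity; alternative estimators would
  change $\Omega_c$ values and its tolerance statements together.
* Training is single-device, full-precision, with no learning-rate
  schedule or early stopping beyond best-checkpoint tracking.
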
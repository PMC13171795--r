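---
title: "Proportional-integral feedback stabilization for small CNN classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proportional-integral feedback stabilization for small CNN classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picnet)
```

## The idea

A proportional-integral (PI) controller corrects a system by combining an
instantaneous response to the current error (the proportional term, gain
$K_p$) with a response to the accumulated history of errors (the integral
term, gain $K_i$):

$$u_t = K_p\,e_t + K_i \sum_{k\le t} e_k.$$

The integral term is an *exact* sum — no forgetting factor — which is what
lets a PI controller remove steady-state error in classical control. This
package applies that law at three places in a small convolutional classifier
for grayscale medical-style images (benign vs malignant nodules):

1. **Input intensity regulation** (`regulate_intensity()`): the controlled
   quantity is the mean gray level of the image; the error is
   `target_intensity - mean(image)`; the actuator adds the scalar control
   signal uniformly to every pixel and clips to $[0,1]$. The loop runs for at
   most `max_iterations` discrete iterations with early stopping on a
   tolerance.
2. **PI feature layers** (`manual_pic_forward()`, `auto_pic_forward()`): a
   spatial reinterpretation of the two control paths. The proportional path
   is a high-pass filter (edges, boundaries — the margin features that
   distinguish spiculated malignant nodules), the integral path a smoothing
   filter (wider spatial context, noise suppression). The paths are scaled by
   the fixed gains and fused, either by channel concatenation or as a
   residual sum. In *manual* mode the filters are the fixed 4-neighbour
   Laplacian and the 3x3 box mean; in *auto* mode the two depthwise kernel
   banks are learned by backpropagation while the gains stay fixed.
3. **PI-controlled optimization** (`pi_step()`): the loss gradient is the
   error signal; parameters are updated by
   $\theta_{t+1} = \theta_t - K_p \nabla L(\theta_t) - K_i I_t$ with
   $I_t = I_{t-1} + \nabla L(\theta_t)$, an exact integral of all past
   gradients — unlike momentum or Adam, whose exponential averages forget.

The "integral" in the feature layer is *spatial* integration (a smoothing
receptive field); the integral in the preprocessor and the optimizer is
*temporal* accumulation across iterations. The package keeps these two
meanings in separate modules on purpose.

## Architectures

`build_model()` assembles: optional PI feature layer (input-side, or after a
configurable conv stage) → three to five convolution stages with 2x2
kernels, stride 1 and ReLU → a 1x1 convolution to 2 channels → global
average pooling → softmax over {benign, malignant}. There are no dense or
flatten layers; the 1x1-conv-plus-GAP head keeps the classifier fully
convolutional while producing exactly two logits. A 2x2 max pool follows
every stage except the last (skipped automatically once maps reach 4x4).
2x2 kernels with stride 1 shift the grid by one pixel, so stages use
asymmetric zero padding (right/bottom) to preserve even spatial dims.

Design choices the architecture leaves open, and what this package does:

* **Per-stage channels** default to (16, 32, 64), extended by 128 and 256
  for depths 4 and 5 — small enough for desk-scale experiments.
* **Fusion default**: channel concatenation for the input-side placement
  (the next convolution absorbs the doubled channels) and residual sum for
  mid-network placement (preserves downstream channel counts). Both are
  selectable.
* **Manual kernels**: the canonical high-pass/smoothing pair — 4-neighbour
  Laplacian (centre 4, edge-adjacent −1, corners 0) and the uniform box
  mean — with reflect padding to avoid border ringing. Auto-mode kernels
  initialize from a zero-mean uniform scaled by $1/k^2$ under a seed.
* **Tie-break**: an exact probability tie predicts benign, the conservative
  call.
* **Loss**: two-logit softmax cross-entropy, the exact two-class equivalent
  of binary cross-entropy, keeps the tie-break expressible.

Training defaults follow the reference protocol: Adam, learning rate
$10^{-3}$, weight decay $10^{-4}$, batch size 32, at most 50 epochs,
plateau learning-rate reduction by a factor 0.1, early stopping after 10
epochs without validation improvement. The PI optimizer is available as
`optimizer = "pi"`; with $K_i = 0$ its training loop is bit-for-bit plain
SGD with learning rate $K_p$ (a property the tests assert).

## Controller parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `kp` | proportional gain (dimensionless) | 0.6 | conventional range $[0.1, 1]$; values outside are accepted with a warning |
| `ki` | integral gain (dimensionless) | 0.05 | conventional range $[0.01, 1]$; `ki = 0` disables integral action silently |
| `target_intensity` | desired mean gray level | 0.5 | on the normalized $[0,1]$ scale |
| `max_iterations` | preprocessor loop budget | 1 | the grid also explores 5 and 10 |
| `tolerance` | early-stop on the absolute error | $10^{-3}$ | 0 means "always run the full budget" |

The published grid (`default_gain_grid()`) is $K_p \in \{0.4, 0.6, 0.8,
1.0, 1.5\}$, $K_i \in \{0.05, 0.1, 0.3, 0.5, 0.8\}$, target $\in \{0.5,
1.0\}$, max iterations $\in \{1, 5, 10\}$. `run_grid_search()` ranks cells
by validation F1 with ties broken toward smaller $K_i$, then smaller $K_p$
(prefer-conservative), and touches the test split exactly once.

## Stability analysis

With the uniform-additive actuator the mean-intensity loop is linear before
clipping: writing $x$ for the deviation of the mean from the target and $I$
for the accumulator,

$$x' = (1 - K_p - K_i)\,x + K_i I, \qquad I' = I - x.$$

`stability_margin()` classifies the loop by the spectral radius of this
2-state companion matrix. When $K_i = 0$ the accumulator is disconnected
from the mean dynamics — its unit eigenvalue is unobservable — so the scalar
factor $|1 - K_p|$ is used instead; otherwise every pure-proportional loop
would be labelled marginal while its mean demonstrably converges. The same
construction classifies the PI *optimizer* on the scalar quadratic loss
(`pi_quadratic_stability()`). Tests check both classifications against
long simulations over gain grids.

Convergence speed is bounded by the spectral radius: with $K_p = 0.2$ the
contraction factor is $0.8$ per iteration, so ten iterations reduce an
initial gap only by a factor $\approx 0.11$ — small conservative gains
cannot reach tight tolerances in few iterations, and a non-zero $K_i$
overshoots before it helps. This matters when interpreting short-budget
runs of `regulate_intensity()`.

### What the integral term does and does not do

A fixed-point analysis of the optimizer on a quadratic loss with a constant
bias $b$ added to every *observed gradient* shows that both plain gradient
descent (any learning rate) and the PI rule settle at $\theta = -b$, with
the PI integral state decaying to zero: an integrator rejects disturbances
that enter at the plant input, but a bias in the *measurement* (here, the
gradient) shifts every fixed point equally. The package's
`compare_optimizers()` includes this biased-quadratic toy; the tests assert
the fixed-point facts rather than a bias-cancellation claim. What *does*
distinguish the exact integrator from momentum-style exponential averages
is its memory: `integral(T) − integral(T−k)` equals the exact sum of the
last $k$ gradients, asserted to machine precision. On long optimization
paths the exact memory also produces classical integrator windup — the
logistic toy shows it, and the tests pin that behavior down.

## The synthetic data generator

`generate_nodule_images()` emulates the structure of a chest-CT nodule
classification dataset at desk scale: a dark background, two bright
lung-field ellipses, and one nodule per image. The benign and malignant
renderers are *identical* except for the amplitude of a seeded sinusoidal
radial perturbation of the nodule margin (three random integer frequencies
in 5–12 with random amplitudes and phases). That makes margin roughness the
class-discriminating signal by construction — mirroring spiculation, the
high-frequency boundary irregularity that marks malignancy — and makes the
"spiculation 0" case exactly class-indistinguishable, which the tests
verify with a margin-roughness statistic. Gaussian pixel noise, a per-image
global brightness offset, class imbalance (the `"imbalanced"` preset uses
the source dataset's 120:416 image-level ratio), and a heterogeneity mode
(per-image contrast scaling plus a background gradient) emulate acquisition
variability.

What the generator does **not** emulate: Hounsfield-unit calibration,
scanner physics, anatomy beyond two ellipses, nodule-free slices,
inter-annotator noise, or the covariate shift between real datasets.
Passing tests on this generator therefore demonstrate that the mechanisms
behave as designed on a controlled task — not that the same accuracy gains
would appear on real CT data.

`augment_images()` implements horizontal flips, additive brightness (with
clipping) and integer-pixel translation (zero fill), and only accepts the
training split — the type-level guard against evaluation leakage.
`split_dataset()` allocates per class by largest-remainder rounding (ties
toward train, then val, then test): 1,122 images at 80/10/10 give
898/112/112.

## Desk-scale experiment protocol

The harness used by the acceptance-level experiments is 400 synthetic
images at 64x64 (spiculation 0.6, noise SD 0.05), stratified 80/10/10
splits, batch 32, Adam with learning rate $10^{-3}$, and a 40-epoch budget
with early stopping (patience 10). Forty epochs keeps a full
plain-vs-PI-layer comparison (15 training runs) inside roughly twenty
minutes on one CPU while staying below the saturation point of the easiest
configurations, so differences between configurations remain visible. The
vignette-level examples and unit tests use much smaller sets (8–36 images
at 32x32) that exercise the code paths without the compute.

## Evaluation protocol

`classification_metrics()` computes accuracy, precision, recall and F1 from
confusion counts, reporting a metric as `NA` (undefined) when its
denominator is zero rather than coercing to 0. `wilson_ci()` implements the
Wilson score interval, which stays inside $[0,1]$ and behaves correctly at
$\hat p \in \{0, 1\}$ — the reason it is preferred over the normal
approximation when metrics sit near 1. `bootstrap_metric()` resamples the
test set with replacement under a seed (undefined-metric resamples are
excluded and counted), and `significance_suite()` runs the global
Kruskal-Wallis test plus the pairwise Wilcoxon signed-rank matrix on paired
bootstrap vectors (same resample indices across models; all-zero-difference
pairs are flagged degenerate with p = 1). `roc_curve()` sweeps thresholds
over distinct scores with trapezoid AUC; a test cross-checks it against the
concordant-pair (Mann-Whitney) identity and against an independent ROC
implementation.

```{r wilson}
wilson_ci(0.99, n = 116)
wilson_ci(1.00, n = 116)
```

## Numerical choices and degenerate inputs

* Error sign convention: `e = target - measured`, so positive error
  brightens.
* The preprocessor state is per image; the accumulator never carries across
  images or batches.
* Reflect padding is mirror-without-edge-repeat; its exact adjoint is used
  in backpropagation so finite-difference gradient checks pass at 1e-6.
* Max-pool ties resolve to the top-left element; argmax probability ties
  predict benign.
* Undefined metrics are `NA`, never 0; bootstrap excludes and counts them.
* Non-finite errors, gradients, pixels and losses are rejected with
  diagnostics naming the step, parameter path, or epoch.
* An optional anti-windup clamp on the optimizer integral exists but is off
  by default (the faithful exact-integrator rule).

## What the desk-scale experiments do and do not show

At the frozen protocol the input-side and mid-network manual PI layers
consistently reach higher test accuracy than the plain CNN on the
imbalanced preset, where the plain network lingers in an all-malignant
regime: the structured high-pass path supplies the margin features the
plain network takes far longer to discover. This reproduces the *direction*
of the reported stabilization benefit, not its magnitudes.

The high-integral-gain recall collapse does **not** reproduce reliably at
desk scale: with residual fusion the heavy smoothing path is an additive
handicap that the downstream stages learn around, and at the full 50-epoch
budget every gain regime solves the synthetic task completely. The
acceptance suite asserts the collapse as a majority-of-seeds comparison and
the corresponding test documents the failure honestly; the acceptance
script reports the measured mean recalls for both gain regimes so the
(small) effect size is visible.

## Known limitations

* The CNN stack is plain R plus compiled kernels on one CPU: practical for
  64x64 desk-scale studies, not for 512x512 production training.
* Auto-mode gains are fixed multipliers; only the kernels learn. Learned
  per-channel gains are out of scope.
* The generator's difficulty is controlled and moderate; conclusions about
  *relative* optimizer/layer behavior transfer qualitatively, absolute
  accuracies do not.
* High-gain regimes interact with clipping in the preprocessor; the
  stability classification describes the linear (pre-clipping) loop.
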
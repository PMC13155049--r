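---
title: "Recurrent gated channel attention for dual-branch histopathology classification: model, explanations, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent gated channel attention for dual-branch histopathology classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cramnet)
```

## The model

Binary classification of H&E-stained histopathology patches (benign vs
malignant) with a deliberately small, interpretable architecture. Two
convolutional backbones process the same patch in parallel; each ends in
global average pooling, producing embeddings $f_A \in \mathbb{R}^{D_A}$ and
$f_B \in \mathbb{R}^{D_B}$. The concatenation $X = [f_A; f_B]$ is refined by
a two-step sigmoid-gated channel attention block with an identity residual:

$$A_1 = \sigma(f_1(X)), \qquad Y' = \mathrm{ReLU}(X \odot A_1)$$
$$A_2 = \sigma(f_2(Y')), \qquad Z' = \mathrm{ReLU}(Y' \odot A_2)$$
$$F = X + Z'$$

Each gating transform $f_k$ is a small two-layer dense network
(input $\to$ hidden, ReLU $\to$ output at feature length) with its own
weights — the two steps are unshared, matching the two distinct weight sets
of the training pseudocode. The refined feature $F$ feeds a single dense
layer of size 2 with softmax. The first gate acts like squeeze-and-excitation
channel attention; the second sees the already-modulated signal $Y'$, so its
weighting is contextual — a two-step unrolled recurrence. The residual
guarantees that the block can never destroy information: $F_i = X_i$ wherever
$X_i \le 0$ and $F_i \ge X_i$ elsewhere (both properties are tested).

With all gate weights zero and biases zero, $\sigma(0) = 0.5$ gives the
neutral closed form $F = X + \mathrm{ReLU}(0.25\,\mathrm{ReLU}(X))$, which is
exactly how the block starts training: weights are He-normal, all biases 0,
so the initial attention is neutral and the network behaves like plain
fusion scaled by 1.25 on positive channels.

### Design choices that were genuinely open

* **Gating hidden width.** A full-width gating layer at a 2560-long fused
  feature costs 6.55 M parameters per layer, which is incompatible with
  keeping the attention block and head in the low millions. The hidden width
  is therefore configurable; `build_model()` defaults to a tenth of the
  fused width (minimum 32), and `init_cram()` accepts any width including
  full width.
* **Vector vs 1×1 spatial map.** The fused feature is treated as a plain
  vector. A 1×1×C map with 1×1 convolutions is mathematically identical;
  nothing is lost.
* **Recurrence depth.** Fixed at two steps by default; `init_cram(steps =)`
  exposes the loop count, and `attention_mode = "single_step"` gives the
  one-pass squeeze-and-excitation-style ablation.
* **Loss.** A size-2 softmax with categorical cross-entropy, the
  two-class formulation of binary cross-entropy (identical gradients).
* **Cyclic learning-rate shape.** Only the oscillation range is prescribed,
  not the waveform; we use the simplest triangular cycle with period 4
  epochs (high, mid, low, mid).
* **Freeze schedule.** "All but the final few layers for the first 3
  epochs" is interpreted as: attention block, head, and each backbone's
  last conv block trainable from epoch 1; everything unfrozen from epoch 4.
  The schedule is a configurable list of (epoch, patterns).
* **Dropout.** Available (`dropout_p`) but off by default; with early
  stopping and a separable task it adds nothing.
* **Tie rule.** A score of exactly 0.5 classifies malignant, favoring
  sensitivity — the clinically conservative direction.

## The training loop

Adam with L2 weight decay (default 1e-5) applied to the head and attention
weight matrices, batch size 16, at most 50 epochs, early stopping on
validation loss with patience 5 and best-weight restoration, online
augmentation of training batches only (±90° rotations, horizontal/vertical
flips, color jitter clipped back to [0,1]), and per-channel standardization
with statistics computed from the training partition only (the leakage-free
convention; validation and test reuse training statistics). Everything is
driven by explicit seeds: a master seed fans out to per-component streams
via `derive_seed()`, so datasets, initializations and batch orders are
individually reproducible and bit-identical across runs.

The default learning-rate range (1e-4 to 1e-5) is a fine-tuning range,
appropriate when backbones start from pretrained weights. The package's
experiments train the small built-in backbone from scratch, for which that
range is an order of magnitude too conservative; the desk-scale experiments
therefore use 5e-3 to 5e-4, a standard from-scratch Adam range, chosen once.

The engine itself is plain R matrix algebra: a 3×3 same-padded convolution
is nine index-gathers and matrix products (so everything runs in BLAS),
pooling and global averaging are cached index maps, and the backward pass is
written by hand. Analytic gradients are verified against central finite
differences both for the attention block alone (relative error < 1e-4, part
of the acceptance suite) and for the full network in development.

## Explanations

**Grad-CAM.** For each branch, the map is
$\mathrm{ReLU}(\sum_c \alpha_c A_c)$ where $A_c$ are the channels of the
branch's final convolutional activation (the last map before global average
pooling) and $\alpha_c$ is the spatially averaged gradient of the
target-class *pre-softmax logit* with respect to that map (the standard
convention; probabilities saturate). Because the embedding is the spatial
mean of that map, $\alpha_c$ is exactly the logit's embedding gradient
divided by the map area, which the attention block's backward pass provides.
Maps are bilinearly upsampled to image size and max-normalized. The two
branch maps are combined as $w_A \cdot \text{map}_A + w_B \cdot
\text{map}_B$, where the weights are the absolute additive shares of the
class logit: the head is linear in $F$, so
$s_{branch} = \langle w_{head}[\text{slice}], F[\text{slice}]\rangle$
decomposes the logit exactly; $w = |s|/(|s_A|+|s_B|)$, with 0.5/0.5 when
both shares vanish. An all-zero map is a legitimate output (a branch the
head ignores), not an error.

**Superpixel Kernel SHAP.** The image is oversegmented into ~50 superpixels
by a compact SLIC-style procedure (grid-initialized k-means on
(r, g, b, y, x) with the usual compactness weighting, plus a connectivity
cleanup that merges stray fragments into their dominant neighbor). Each
superpixel is a player; the value function is the model output on the image
with absent superpixels painted with the image's **global** per-channel mean
color — a whole-image mean rather than per-region means, so the baseline
leaks no region content (the choice is configurable by masking manually).
The empty-coalition output is the baseline; the attribution target is the
malignant pre-softmax logit. `kernel_shap()` solves the Shapley-kernel
weighted least squares under the efficiency constraint (so
$\text{base} + \sum\phi_i$ equals the full-image output exactly), enumerates
all proper coalitions whenever the sample budget covers $2^K - 2$ (in which
case it equals the exact Shapley values — verified to 1e-6 against
`exact_shapley()`, a brute-force $2^K$ enumeration guarded at $K \le 12$),
and otherwise samples coalition sizes from the kernel distribution. The
default budget of 2048 evaluations suits a standalone analysis; the batch
experiments in this package use 300 evaluations per image, which is ample
for the *sign* of an aggregate over ~10 planted-region superpixels (the
quantity the validation asserts) if not for publication-grade per-region
values.

**Agreement metrics.** Saliency maps are binarized at 30% of their maximum
(inclusive, so the peak always survives) and compared with the planted mask
by IoU and Dice (both defined as 1 when both masks are empty); the pointing
game asks whether the maximal pixel (row-major tie-break) falls inside a
nonempty mask, so benign images are excluded from pointing averages; the
normalized overlap is the fraction of saliency mass inside the mask.
McNemar's paired test reports the textbook $(b-c)^2/(b+c)$ statistic, and
because the asymptotic test is unreliable at the discordant counts typical
of near-ceiling classifiers, it defaults to the exact binomial p-value
whenever $b + c < 25$.

## The synthetic study system

Real pathology data cannot ship with a package and pathologist annotations
are not reproducible; the generator provides a controlled stand-in with
exact ground truth. Benign patches: a pale eosin-pink background with
Gaussian texture noise and 5–15 sparse, round, low-contrast blobs; the
ground-truth mask is identically zero. Malignant patches: the same
background and benign texture plus 1–3 clusters of 20–60 overlapping,
irregular (sinusoidally perturbed radius), strongly hematoxylin-dark blobs;
the union of the cluster footprints after morphological closing is the mask.
This mirrors the cue that drives real malignancy calls — densely packed dark
nuclei — while the planted mask makes every localization metric exact. The
default contrast guarantee (mean grey intensity inside vs outside the mask
differs by more than 0.2) is asserted per image in the tests; measured
differences are ≈ 0.4.

Patients are synthetic groups of `images_per_patient` consecutive images;
splitting assigns whole patients, so patient-level leakage is structurally
impossible, and partition sizes follow the requested fractions exactly when
every patient has one image (10,000 unit-group images at 80/10/10 give
exactly 8,000/1,000/1,000).

What the generator does **not** emulate: stain variability between
laboratories (stain normalization is mentioned but unspecified in the
source protocol and is deliberately not implemented — only per-channel
standardization), magnification levels, tissue architecture (glands, ducts,
stroma), artifacts (folds, blur, pen marks), and any realistic relationship
between images of one "patient". Passing tests therefore demonstrate that
the architecture, optimizer, explanation stack and metrics are implemented
correctly and behave as designed on a separable, controlled task — not that
the model would reach any particular accuracy on real slides.

## Problem sizes and validation design

The package's experiments run on one CPU at "desk scale", chosen so the full
pipeline (data, training, both explanation methods, all metrics) executes in
minutes: 200/50/50 training/validation/test patches of 64×64, a two-branch
model of ~24k parameters, 10 training epochs, 50 held-out malignant patches
for saliency evaluation, 300 SHAP evaluations per image. At these sizes the
classifier reliably reaches 100% test accuracy within a few epochs — the
synthetic task is intentionally easy, because the assertions concern
mechanism, not difficulty:

* test accuracy ≥ 95% within 10 epochs (backed by the generator's
  separability property: a two-feature logistic model already exceeds 95%);
* Grad-CAM pointing-game accuracy ≥ 0.8 on the trained model versus
  chance-level-or-below for freshly initialized, untrained models (the
  comparison point is the planted-mask area fraction, ≈ 0.19; the baseline
  is averaged over several initializations because a single untrained
  network's saliency is highly init-dependent);
* positive total SHAP attribution on planted-region superpixels for ≥ 90%
  of correctly classified malignant patches;
* a paired five-seed convergence comparison in which the two-step attention
  never converges slower than plain fusion on average, with the single-step
  variant in between (sign-style tendency with ties allowed, not a
  significance claim — five seeds cannot support one).

Published large-scale figures on the external dataset (99.9% accuracy,
AUC ≈ 1.0, specific epoch counts, FLOPs/FPS, and annotated-slide IoU or
pointing values) depend on that data, pretrained backbones and GPU training,
and are out of scope here; the property-based suite above replaces them.

## Numerical notes and limitations

* Attention masks are mathematically in (0,1); in floating point a sigmoid
  saturates to exactly 1.0 beyond logits of ~37, so strict-interval checks
  apply to moderate inputs.
* Softmax and cross-entropy are computed with row-max subtraction and a
  1e-12 probability floor.
* `normalize_images()` uses the population (1/N) standard deviation so a
  self-standardized collection has unit variance exactly; a zero-variance
  channel is a hard error naming the channel.
* The SLIC-style segmentation is deterministic (grid initialization, fixed
  iteration count); the `seed` argument exists for interface uniformity.
  The achieved region count can deviate from the target (bounded within
  [0.5, 2]×) because the initial grid is rectangular and small fragments are
  merged.
* Bilinear upsampling of Grad-CAM maps bleeds activation across a one-cell
  margin at the coarse resolution; support tests account for that margin.
* A *single* untrained network is a poor pointing-game null: its score is
  close to bimodal in the initialization. The planted clusters are the
  dominant contrast structure, so an untrained network's final activation
  maps differ between cluster and background, and the sign of the
  common-mode channel gradient through the random head decides whether the
  ReLU'd class-activation map survives over the clusters (pointing ≈ 1) or
  over the background (pointing ≈ 0). Inheriting the trained model's
  normalization statistics biases the flip further toward spurious
  cluster-pointing. The stable, meaningful baseline is the average over
  several fresh initializations on raw inputs, which sits at or below the
  mask-area chance rate; both the tests and the acceptance script use that
  ensemble protocol. The general lesson: untrained saliency baselines
  should be ensembled over initializations and must not borrow any artifact
  of training.
* Training the attention block without its residual is supported for
  ablation but not recommended; it is known to be less stable, and the
  package only asserts that it runs.
* The pure-R engine is adequate for desk-scale experiments (a training
  epoch on 200 64×64 patches takes ~1 s); it is not a general-purpose deep
  learning framework, and real pretrained backbones are out of scope —
  any feature extractor honoring the embedding contract can be plugged in
  as a `backbone_spec`-like adapter.
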
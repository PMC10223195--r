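---
title: "Cross-fusion transformer segmentation of OCTA angiograms: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-fusion transformer segmentation of OCTA angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octafuse)
```

## The segmentation problem

En-face OCTA angiograms visualize retinal blood flow as bright, branching
vascular trees on a speckled dark background. Capillaries are thin (often a
single pixel), low-contrast, and embedded in multiplicative speckle, so
plain convolutional encoder–decoder networks tend to fragment them: the
receptive field is local, and the standard U-Net skip connection only copies
same-scale features, so no pathway lets coarse vessel context repair
fine-scale breaks. The architecture implemented here attacks exactly that
coupling: the four encoder scales are fused jointly by a cross-scale
attention module before they reach the decoder, and each fused skip is gated
channel-wise against the decoder state it joins.

## Network structure

The backbone is a four-level U: per level two 3×3 convolutions, each
followed by batch normalization and ReLU; 2×2 max-pooling between encoder
levels; bilinear ×2 upsampling followed by a 3×3 convolution (plus BN and
ReLU) between decoder levels; a 1×1 convolution produces single-channel
logits. The deepest encoder output doubles as the start of the decoding
path, so all four scales contribute skip connections, including a
same-resolution fusion at the deepest level. Convolutions that feed directly
into a batch-norm layer carry no bias: the normalization's mean subtraction
makes such a bias exactly gradient-dead, and carrying dead parameters would
falsify the package's gradient-coverage guarantee.

Two design points of the backbone are not dictated by the architecture
family and were fixed as follows. Downsampling is max-pooling and upsampling
is bilinear-then-convolution — the standard U-Net choices this family builds
on. The channel widths of the reference configuration are (52, 104, 212,
416). They were calibrated once against the architecture's published size of
14.1 M trainable parameters: a uniform ~1.64× scaling of the conventional
(32, 64, 128, 256) ladder, rounded to multiples of the head count, with the
third level nudged by one head-width because the rounding lattice otherwise
brackets the target (14.01 M below, 14.20 M above). `count_parameters()`
on `reference_config()` reproduces 14 136 073 ≈ 14.1 M.

## The cross-fusion transformer (ECT)

Each encoder output `X_i` is layer-normalized per spatial position over its
channels (the "regularization" step; layer normalization is the
transformer-standard reading), then projected by three 1×1 convolutions to
queries, keys and values with the scale's own channel width. All projections
are shrunk to a shared token grid of `k = (H/r)·(W/r)` positions — bilinear
interpolation by default, grouped max-pooling as the ablation alternative —
and flattened to `k × C_i` token matrices. Keys and values are concatenated
across the four scales along the embedding axis into `k × ΣC_j` matrices.

Attention is computed per head on the *channel* axes: with per-scale,
per-head width `d_i = C_i / heads` and `d_Σ = Σ d_j`, the score matrix is

    A = softmax_rows( Q'ᵢᵀ K' / sqrt(d_Σ) )        (d_i × d_Σ)

and the head output is `(A V'ᵀ)ᵀ`, a `k × d_i` token matrix. Three
decisions here deserve a note:

* **Scaling.** The scaled-dot-product family divides scores by the square
  root of the key width; the implementation uses `1/sqrt(d_Σ)`. A linear
  (non-root) scaling would change the softmax temperature with width and has
  no precedent in the attention literature this module descends from.
* **Softmax axis.** The weights must lie on the values, whose columns index
  `d_Σ`; each row of the score matrix is therefore normalized across the
  `d_Σ` axis. Every row summing to one is asserted by the test suite.
* **Reduced queries.** Queries are token-reduced like keys and values (the
  `k × d_i` typing), not kept at full length. This makes the attention
  output a `k`-token object, which is exactly what the restoration step
  expects; the alternative full-length-query reading would make the
  residual of the refinement stage ill-typed.

Head outputs are concatenated and merged by one linear map per scale (the
conventional multi-head merge; the architecture family does not specify
one). The merged tokens are reshaped to the token grid, bilinearly
upsampled to the scale's resolution and passed through a 1×1 convolution —
this is the "upsample + 1×1" restoration — giving `Â_i`, and the fused
skip is the residual refinement

    E_i = s + Conv3×3(ReLU(BN(s))),   s = X_i + Â_i,

with the operator order exactly normalization → activation → convolution.
With zero attention contribution and a zero-initialized refinement
convolution this is an exact identity, which the tests assert to machine
precision.

The score matrices are `d_i × d_Σ` regardless of image size: once `k` is
fixed, doubling the input side leaves every attention matrix unchanged (the
package records these dimensions on each forward pass and the suite checks
them at two image sizes). The default reduction factor is 16 per axis
(`k = HW/16²`, 361 tokens on 304×304 input); 4 and 8 are supported for the
ablation grid. For factors below 8 the shared token grid is finer than the
deepest scale's own grid, so the internal resize interpolates that scale
*up* — the only reading under which a shared-`k` concatenation of all four
scales stays well-defined. The exported `reduce_tokens()` keeps the strict
target ≤ source contract and errors instead.

## The channel gate (ECCA)

Skip and decoder features are squeezed to per-channel descriptors by global
average pooling followed by a sigmoid; two `C_i × C_i` linear maps fuse
them, and a second sigmoid forms the gate:

    N_i = L1 σ(AvgPool(E_i)) + L2 σ(AvgPool(D_i)),   E'_i = σ(N_i) ⊙ E_i.

Both squashings are intentional and kept. Because the gate lies strictly
inside (0, 1), every output magnitude is strictly below its input — a
property the suite sweeps over random draws — and the gate value is constant
across the spatial positions of a channel. The descriptor could additionally
aggregate a max-pool (the "both poolings" variant discussed in the source
family without an accompanying equation); this is exposed as an off-by-default
option of `channel_descriptor()` and not used by the model, since the
equations are normative. In the `ecca` ablation variant the gate is applied
to the raw encoder features, with the decoder feature as the second
descriptor input — the same wiring, minus the transformer.

## Metrics

All eight measures reduce to the confusion counts of a thresholded score
map; the binarization threshold defaults to 0.5 on the sigmoid output (the
recipe does not state one; 0.5 is the convention for probability outputs and
is configurable). Kappa uses the expected-agreement expansion from the
confusion-matrix marginals, which the tests verify against the standard
two-marginal Cohen form at 1e-12. The G-mean is implemented as
`sqrt(sen · spe)`: the printed formula in the source family omits the root
its own citation defines, and reported values near 0.85 alongside
sensitivities and specificities near 0.78/0.97 are only consistent with the
root form; a `gmean_no_sqrt` switch reproduces the bare product. AUC is the
rank-based Mann–Whitney statistic with half credit for ties. Degenerate
denominators (empty prediction class, single-class ground truth, constant
tables) yield `NA`, never a silent zero. Evaluation covers the full frame —
en-face OCTA images carry signal everywhere, so there is no field-of-view
mask — and aggregates per-image means by default, with pixel pooling as an
alternative; which of the two the published tables use is not stated, so
both are first-class.

## Training recipe

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) with learning rate 6e-4, weight
decay 1e-4 added to the gradients, batch size 2, and a poly schedule
`lr·(1 − step/max_steps)^0.9` stepped per iteration (per-iteration stepping
is the semantic-segmentation convention; at these run lengths per-epoch
stepping is indistinguishable). The loss is mean binary cross-entropy
computed stably from logits; supervision is single-output at full resolution
(no deep supervision is described for this family). Augmentation is a single
uniform rotation in [−10°, 10°] applied identically to the image and its
masks, training mode only, with masks re-binarized at 0.5 after
interpolation. All randomness — initialisation, shuffling, augmentation —
derives from one seed, and two runs with the same seed are bit-identical.
The published hyperparameter search is not re-run; its best values are the
hard defaults.

## The synthetic generator

`synthetic_sample()` emulates the geometry and photometry that make OCTA
segmentation hard at desk scale: branching bright trees (random-walk
branches that split at their tips into two thinner children, so a depth-d
tree has at most `2^d − 1` branches per root), width-dilated pixel masks
with one-pixel centerline masks (the two annotation levels of OCTA
datasets), mild blur, and multiplicative speckle. Default parameters (three
roots, split probability 0.5, depth 3, root width 4 px on a 64×64 canvas)
were chosen once so that the vessel-pixel fraction lands in the 5–25 % band
typical of en-face angiograms; walks reflect at the canvas border so trees
stay in frame. Everything is a pure function of (parameters, seed), and
datasets regenerate byte-identically.

What the generator does *not* emulate: physically realistic OCT speckle
statistics, the foveal avascular zone, projection and shadow artifacts,
pathology, or inter-device contrast differences. Passing tests on synthetic
data therefore demonstrate that the architecture, gradients, recipe and
metrics are implemented correctly and that the model family can fit vascular
structure — they say nothing about clinical performance on real angiograms,
which requires the registration-gated OCTA benchmarks and GPU-scale
training.

## Numerical choices and degenerate inputs

* Batch statistics use population variance with ε = 1e-5 and running-stat
  momentum 0.1; evaluation mode uses the running statistics, making
  inference deterministic.
* Max-pooling breaks ties toward the first matching position so gradient is
  routed to exactly one source pixel.
* Bilinear resampling uses half-pixel centers with clamped edges; every
  interpolation row sums to one, so constants are preserved in both
  directions.
* Weight initialisation is He-scaled Gaussian for convolutions and
  Xavier-scaled for linear maps; normalization affinities start at (1, 0).
* Images whose sides are not divisible by 8 are reflect-padded for
  prediction and cropped back; `encode()` itself rejects them.
* A non-finite training loss aborts with a diagnostic rather than continuing
  silently.

## Problem sizes in the shipped tests

The suite exercises the pipeline at deliberately small scale: micro
configurations with widths (4, 8, 12, 16) for gradient and wiring checks
(verified against central differences per operation and through the whole
network), 64×64 synthetic images with base width 8 for the trainability and
overfit checks (eight images, up to 200 epochs, three seeds), and a single
304×304 forward pass for the token-count contract. The reference
configuration is only ever *constructed* (for the parameter budget), never
trained in the tests. These sizes are the package's own choice of a
desk-scale regime in which every property is checkable in minutes on one
core.

## Known limitations

The implementation is CPU-only and single-threaded beyond BLAS; training the
reference configuration on real 304×304 datasets is out of its intended
scope. Checkpoints serialize R objects and are not interchangeable with
other frameworks. The FLOPs accounting of the source family is not
reproduced (its counting convention is unstated); only the parameter budget
is. Benchmark comparisons against other networks require external data and
re-implementations and are likewise out of scope.
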
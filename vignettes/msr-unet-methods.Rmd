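---
title: "MSR-UNet: multi-scale reconfiguration self-attention for 2D segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSR-UNet: multi-scale reconfiguration self-attention for 2D segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Organs and lesions in CT/MR slices vary enormously in size and shape: a liver
spans half the field of view while an aorta cross-section is a few pixels
wide.  Window-based self-attention (the Swin family) keeps the cost of
attention linear in image size by restricting each query to a local window,
but a fixed single-scale window cannot simultaneously resolve fine boundaries
and model the long-range dependencies that large structures require.

`msrunet` implements a U-shaped segmentation transformer whose attention
operator — multi-scale reconfiguration self-attention (MSR-SA) — restores
both properties at fixed cost.

## The MSR-SA operator

For a feature map with `N' = H x W` tokens and `C` channels:

1. **Grouping.** Channels are split evenly into `G` groups (`C' = C/G`); each
   group runs an independent attention head.
2. **Localization.** Group `i` tiles the grid into non-overlapping `S_i x S_i`
   windows (`M_i = ceil(H/S_i) * ceil(W/S_i)` of them, after zero-padding on
   the bottom/right when `S_i` does not divide the extent).
3. **Dilated sampling.** Inside every window an `M x M` point grid is sampled
   at offsets `{0, D_i, ..., (M-1) D_i}` with dilation
   `D_i = (S_i - 1)/(M - 1)`, so exactly `M^2` points span the window
   whatever its size (`M = 7` by default).
4. **Cross-window fusion.** Sampled points are projected to keys and values
   by per-group 1x1 convolutions (`W^K`, `W^V`), then same-position features
   are fused **across windows** by a symmetric reduction `sigma` — max
   pooling by default, with mean and a learnable linear weighting available.
   Each fused key therefore summarizes one relative position across the
   whole image: long-range context inside a local-window budget.
5. **Grouped attention.** All `N'` tokens act as queries (projection `W^Q`);
   group `i` computes `softmax(Q K^T / sqrt(h_i)) V` against its `M^2` fused
   keys, with `h_i = C'` (the conventional per-head scaling; the operator
   leaves it unspecified otherwise).
6. **Concatenation.** Group outputs are concatenated along channels; the
   output shape equals the input shape.

Because window sides grow with the group index (default `D_i = 2^(i-1)`,
i.e. sides 7, 13, 25, ... for `M = 7`, clamped to the largest window that
fits the grid) the groups see the image at ascending granularities: small
windows preserve local detail, large windows carry coarse long-range
structure.  The key count per group is always `M^2`, so changing the
schedule changes neither compute nor parameter count.

Two schedule presets reproduce the single-scale ablations: `low` sets every
`D_i = 1`, and `high` gives every group a single window covering the grid
(the smallest valid `S >= max(H, W)`).

### Choices the operator description leaves open

* **Window count in 2D.** The per-group window count is
  `ceil(H/S) * ceil(W/S)` — square windows tile both axes; maps need not be
  square.
* **Padding.** Non-divisible extents are zero-padded bottom/right.  Padded
  sample positions are excluded from the fusion reduction; positions that are
  padding in *every* window (possible when a window is clamped to a grid
  smaller than `S`) are masked out of the attention softmax entirely.
* **Group-local keys.** Queries of group `i` attend only to that group's
  fused keys; both paths (key and value) use the same fusion operator.
* **Fusion default.** Max pooling is the default; mean and linear fusion are
  options.  Linear fusion learns one weight per window and is therefore tied
  to the geometry it was built for.
* **Initialization.** Attention projections use a truncated normal
  (sd 0.02); main-path linear layers (adapters, expansion, head) use
  Glorot-style fan scaling so activation magnitude survives the
  unnormalized decoder path — with a uniform 0.02 the logits collapse to
  ~1e-4 and SGD stalls.

## Architecture

* **Encoder.** A 7x7 stride-4 overlapping convolution embeds the grayscale
  slice into tokens at 1/4 resolution (layer-normalized), followed by four
  stages of pre-norm reconfiguration transformer blocks
  (`x + MSR-SA(LN x)`, `x + FFN(LN x)`) separated by overlapping patch
  merging (3x3 stride-2 convolution, channels widened per the stage plan).
  The feed-forward expands 4x, applies a 3x3 depthwise convolution on the
  spatial grid, GELU, and contracts.
* **Context bridge.** All four stage maps are projected to the widest
  stage's width, flattened, and concatenated along tokens; `d` (default 4)
  reconfiguration blocks refine the packed sequence, and the result is split
  and restored to the per-stage shapes.  Attention windows inside the bridge
  are defined on each stage's own 2D grid (a window over a concatenated
  multi-resolution sequence has no spatial meaning); the blocks' weights are
  shared across stages, which is what couples them.  The `d` loops are
  distinct blocks, not a shared-weight recurrence.
* **Decoder.** Three stages of patch expanding (linear width adjustment +
  channel-to-space), concatenation with the bridge-refined skip, a linear
  reduction, and reconfiguration blocks; a final 4x channel-to-space
  expansion and per-pixel linear projection produce `K` logits at input
  resolution.  For a 224x224 input the encoder grids are 56^2, 28^2, 14^2,
  7^2.

## Losses and metrics

Training minimizes `lambda * L_dice + (1 - lambda) * L_ce` with
`lambda = 0.6` and uniform class weights `w_k = 1/K`; a dice-only mode is
provided for datasets conventionally trained that way.  The dice loss uses
squared-magnitude denominators (`sum p^2 + sum g^2`) with an additive
`1e-5` smoothing; the cross-entropy is the per-class binary form averaged
over all `K` classes and `N` pixels (the printed form leaves the class index
free), with probabilities clamped to `[1e-7, 1 - 1e-7]`.

Evaluation reports the Dice similarity coefficient (percent; a class empty
in both masks scores 100, empty in exactly one scores 0; the summary is the
mean over foreground classes) and the Hausdorff distance between boundary
point sets (classic maximum by default — matching how the benchmark numbers
are labelled — with HD95 available; an empty region yields NaN with a
warning and is excluded from means).  Distances use a Euclidean distance
transform (`EBImage::distmap`) in the isotropic case and explicit point-set
distances under anisotropic spacing; the test suite checks both against an
all-pairs brute-force oracle.

## Training recipe

SGD with momentum 0.9, weight decay 1e-4, initial learning rate 0.05 and a
per-iteration poly schedule `lr = 0.05 * (1 - t/T)^0.9` (power 0.9 is the
conventional choice; the recipe states "poly" without a power).  Moderate
augmentation: random horizontal/vertical flips, random 90-degree rotations,
and a small rotation within ±20 degrees (bilinear image / nearest-neighbour
mask).  The best-validation checkpoint is retained.  All randomness derives
from one seed; runs are exactly reproducible.

## The autodiff engine

No deep-learning framework ships with this package's dependency set, so the
network runs on a compact reverse-mode automatic-differentiation tape
(`R/autodiff.R`): tensors are plain R matrices, each operation records a
backward closure, and `t_backward()` walks the reverse topological order.
Dense algebra lands in BLAS; the irregular kernels (depthwise convolution,
dilated gather/scatter, cross-window max fusion) are small C++ routines
under `src/`.  Every primitive is verified against central finite
differences in the test suite, and one end-to-end check confirms the
gradient of the full network matches finite differences through all seven
module layers.

## Synthetic phantoms

The phantom generator emulates the property that makes multi-organ slices
hard: structures at several spatial scales whose single-pixel intensities
are ambiguous.  Each 64x64 phantom (side and class count configurable)
contains, on a background of mean 0.2:

* a **large rotated ellipse** (class 1) whose major diameter (~54-60 px)
  exceeds the widest default attention window at 1/4 resolution
  (13 cells = 52 px) — segmenting it exercises long-range fusion;
* a **thin annulus** (class 2, ~3 px thick) — a boundary-accuracy probe;
* a **small circle** (class 3, radius 2-3 px) — smaller than the `M = 7`
  sample grid, a fine-scale probe.

Foreground means are evenly spaced in `[0.45, 0.85]` with Gaussian noise of
sd 0.1, so neighbouring classes overlap pixel-wise (gaps of 0.2 at 2 sd of
noise) and context is required.  Shapes are rejection-sampled to be
disjoint; the same seed reproduces a phantom bitwise.  What phantoms do
**not** emulate: anatomical texture, partial-volume effects, scanner
artefacts, 3D continuity — phantom results demonstrate that the machinery
learns and evaluates correctly at desk scale, not clinical performance.

## Desk-scale study sizes

The package's own verification (test suite and `scripts/acceptance.R`) uses
a small configuration chosen to exercise every architectural element on one
CPU: 64x64 phantoms, stage widths 16/32/64/128, depth 1 per stage, groups
(2, 4, 8, 8) — so the finest grid carries a genuine ascending dilation pair
— bridge depth `d = 2`, batch size 2, and a few hundred SGD iterations,
evaluated on 20 held-out phantoms.  The benchmark-scale defaults
(224x224, widths 64/128/320/512, depths 2, `d = 4`, 400 epochs, batch 24)
remain the package defaults for real data.  With this smoke recipe the
held-out mean foreground Dice typically reaches the high 80s within 500
iterations; the ascending-dilation default schedule is compared
directionally against the all-`D=1` schedule over three seeds.

## Known limitations

* 2D slices only; volumes are handled slice-wise by the CLI convention.
* CPU-only; throughput is adequate for the smoke scale, not for
  benchmark-scale training.
* No ImageNet pretraining (a flag accepts external weights but nothing in
  the package requires them); no relative position bias; no learned
  sampling offsets.
* Linear fusion ties a model to its build-time input side.
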
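---
title: "Methods: slice-transformer classification and attention saliency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slice-transformer classification and attention saliency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sliceformer)
```

# The model

A 3D grayscale volume (MRI, CT) with $N$ slices is classified in two stages.

**Slice encoding.** Each 2D slice is encoded independently by a pluggable
image encoder. The default is a vision transformer (ViT): the slice is cut
into non-overlapping $p \times p$ patches, each patch is linearly projected
to an embedding of dimension $d$, a learned classification (CLS) token and
learned position embeddings are added, and the tokens pass through a stack of
pre-norm Transformer blocks (layer norm, multi-head self-attention, residual;
layer norm, GELU feed-forward, residual) followed by a final layer norm. The
CLS token's output is the slice feature $f_i \in \mathbb{R}^d$. A 2D residual
network is available as an alternative encoder; it returns the post-pooling
feature vector and no spatial attention. Single-channel slices are replicated
to three channels so that weights trained on natural images remain usable.

**Slice aggregation.** The $N$ slice features are treated as a sequence and
aggregated by a *single* pre-norm Transformer block with its own learned CLS
token; an affine head on the CLS output produces the two class logits.
Because the block has no position embedding by default, the aggregator is
permutation-invariant over slices. Three ablation variants are provided:

* `transformer_adpe` — adds a learned per-slice position embedding, making
  slice order matter;
* `linear` — flattens the $N \times d$ feature matrix (column-major) into one
  affine layer; order matters and the slice count is fixed;
* `average` — mean of the slice features followed by an affine head;
  permutation-invariant but attention-free.

**Saliency.** The aggregator's CLS attention over slices gives per-slice
weights $w_i \ge 0$, $\sum_i w_i = 1$ (register and CLS columns are dropped
per head, each head's row is renormalized, heads are averaged; see
`extractClsAttention()`). The ViT's last-block CLS attention over patches
gives a per-slice $g \times g$ map with the same convention. The two are
fused by `combineAttention()`: each patch map is resized to slice resolution
with *mass-preserving* bilinear interpolation (values renormalized so the
resized map still sums to 1) and scaled by its slice weight. The fused
3D map therefore satisfies two invariants that are checked by the
`AttentionBundle` validity method: each slice's mass equals its slice weight,
and the total mass is 1. This makes the saliency a probability distribution
over the volume, directly comparable across volumes.

**Reference model.** A 3D residual network (depths 18/34/50/101/152, kernels
inflated to $k \times k \times k$) with activation-times-gradient saliency
(`gradCAM3D()`: channel-wise sum of last-stage activations times their
gradients, clipped at zero, trilinearly resized to the input shape) serves as
the conventional end-to-end 3D baseline.

# Parameters, defaults, and rationale

| Parameter | Default | Rationale |
|---|---|---|
| encoder geometry (`vit_small`) | patch 14, side 224, $d=384$, depth 12, 6 heads | standard small self-supervised backbone; 21.6M parameters |
| aggregator | 1 block; heads/feed-forward mapped from $d$ (384 → 12 heads, ffn 384; 512 → 16/512; 768 → 16/768) | one block suffices for a weighted-pooling role and keeps the aggregator at ~0.9M parameters |
| optimizer | AdamW, decoupled weight decay $10^{-2}$ | decoupling keeps decay independent of the adaptive step |
| learning rate | $10^{-4}$ (3D ResNet), $10^{-5}$ (CNN-encoder MST), $10^{-6}$ (ViT MST) | the more pretrained-like/deeper the encoder, the smaller the step |
| batch size | 2 | volume-level training is memory-bound |
| sampling | class-balanced with replacement, epoch = $n$ draws | counters prevalence imbalance without discarding data |
| early stopping | patience 50 on *strict* validation-AUC improvement; best checkpoint restored | ties do not reset patience, so plateaus terminate |
| augmentations | flip, Gaussian noise, rotation (±10°, bilinear), signal inversion, each with probability 0.5 | modality-agnostic, label-preserving |
| synthetic generator | 16 slices of 32×32, prevalence 0.5, lesion contrast 5, noise SD 0.5, in-plane radii 4–8 px, slab 3–6 slices, spacing (3, 0.7, 0.7) mm | study conditions; chosen once, not tuned to outcomes |

All randomness flows through explicit integer seeds (`withSeed()` saves and
restores the global RNG state), so builds, training runs, splits, bootstrap
draws and the synthetic data are bit-reproducible.

# What the synthetic generator emulates — and what it does not

`generateCase()` places one ellipsoidal lesion (random centre, radii and
slice slab) of fixed additive contrast into a Gaussian-noise background and
records the exact mask and slice range. `generateContrastPair()` emulates
pre/post-contrast acquisition (the post image adds the lesion contrast plus
independent noise), and `generateMultireader()` emulates inter-reader
variability by toggling boundary voxels and jittering ordinal ratings. This
is enough to exercise every pipeline stage against known ground truth:
detection is learnable, localization is checkable voxel-by-voxel, and label
derivation rules have exact oracles.

It does *not* emulate anatomy, intensity nonuniformity, partial-volume
effects, motion, or realistic lesion morphology. Absolute performance
numbers on this generator say nothing about clinical performance; they are
software checks.

# Numerical choices and conventions

* **Axis order** is (slice, row, col) everywhere; internal CNN arrays are
  (depth, height, width, channel). Slice identifiers are 0-based in
  metadata, 1-based inside R code.
* **Foreground threshold**: `foregroundCenterCrop()` uses a *strict*
  `>` percentile comparison. On near-constant images the percentile equals
  the constant, so `>=` would select everything; strict `>` isolates genuine
  foreground, and a fully constant image falls back to the geometric centre.
* **Interpolation**: `resizeLinear()` is separable, align-corners linear
  interpolation with clamped fractional positions. Attention maps are
  resized with the mass-preserving variant (renormalized after resizing) so
  the probability semantics survive resampling.
* **Ties and argmaxes**: all argmax conventions (peak slice, peak voxel,
  max-pooling) break ties toward the lowest index, which makes the
  localization proxies deterministic.
* **Degenerate statistics**: the paired DeLong test returns $p = 1$ when the
  variance of the AUC difference is numerically zero (e.g. identical score
  vectors); the bootstrap redraws any resample that loses one class.
* **Lesion-hit proxy**: the global saliency peak counts as a hit if it lies
  in the ground-truth mask dilated by one voxel (26-neighbourhood), which
  absorbs the half-voxel ambiguity created by resizing coarse maps.
* **Pre-norm blocks and exact GELU** ($x\,\Phi(x)$) are used throughout;
  layer-norm epsilon is $10^{-6}$, batch-norm epsilon $10^{-5}$ with
  momentum 0.1.
* **Register tokens** participate in attention but are excluded from the
  patch-attention map (their columns are dropped before renormalization).
* **Subtraction images** default to post-minus-pre; the direction is an
  explicit flagged argument, never inferred.
* **Linear-aggregator flattening** is column-major (R's native `as.vector`),
  i.e. feature-dimension-fastest; it is documented because any fixed choice
  breaks permutation invariance by design.

# Desk-scale sizes

Everything in the test suite and in `runReferenceExperiment()` runs on a
single CPU in minutes by using a deliberately tiny instantiation of the same
code paths: 16-slice 32×32 volumes, a `"tiny"` ViT (patch 8, $d=64$,
depth 2) and a 64-dimensional aggregator. This is a package design choice —
the full-scale geometries (`vit_small`, `vit_base`, depth-50/101 3D ResNets)
are constructed and parameter-audited in the tests but not trained there.

```{r quick-example}
spec <- synthSpec()
case <- generateCase(spec, seed = 7)
case
enc <- buildEncoder(vitConfig("tiny"), seed = 1)
fs <- encodeVolume(enc, case@volume)
agg <- buildAggregator(aggregatorConfig("transformer", embedDim = 64,
                                        nSlices = 16), seed = 2)
out <- aggregateAndClassify(agg, fs)
round(out@sliceAttention, 3)
bundle <- combineAttention(out@sliceAttention, fs@patchMaps, c(32, 32))
sum(bundle@combined)   # fused saliency is a probability distribution
```

# Design decisions on open points

* The 2D CNN slice encoder defaults to depth 18, whose pooled feature is
  512-dimensional — the dimension the aggregator configuration fixes for the
  CNN variant. Deeper bottleneck variants (pooling to 2048) are available
  but require a matching aggregator dimension.
* Mixed-class groups in `stratifiedGroupSplit()` are allowed and always kept
  whole; a split is rejected (naming the offending group) only when no
  whole-group assignment can reach every per-class target within one sample.
* Half precision is recorded in `trainConfig()` for provenance but not
  emulated; all arithmetic is double precision.
* The number of attention heads for non-standard aggregator dimensions falls
  back to 4 with feed-forward width equal to the embedding dimension.

# Known limitations

* Pure-R training is practical only at desk scale; full-scale geometries are
  constructible and auditable but not trainable in reasonable time here.
* No pretrained encoder weights ship with the package; `frozen = TRUE`
  reproduces the frozen-backbone training regime with whatever weights the
  encoder holds.
* The ViT backward pass supports the feature output (as needed for
  classification training); gradients through the attention-map outputs are
  not implemented.
* Saliency is evaluated by proxy (peak-slice and dilated peak-voxel hits),
  not by reader studies.
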
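# sliceformer

Slice-transformer classification and attention saliency for 3D medical
volumes, in pure R.

## The problem

Radiological diagnosis from volumetric imaging (breast MRI, chest CT, knee
MRI) is usually automated with 3D convolutional networks, which train
end-to-end but explain themselves poorly: their gradient-based saliency maps
are coarse and hard to audit. This package implements an alternative: encode
each 2D slice independently with a strong image encoder, aggregate the
per-slice features with a **single-layer Transformer** through a learned
classification (CLS) token, and read the explanation directly out of the
model — the CLS token's attention over slices, fused with each slice's
patch-level attention, is a probability distribution over the volume that
says where the model looked.

The package is aimed at methods researchers and scientific programmers who
want a fully inspectable, dependency-light reference implementation: every
neural component (vision transformer, Transformer aggregator, 2D/3D residual
networks, AdamW) is written in plain R matrix operations with exact
hand-derived gradients, validated against finite differences in the test
suite.

## The model

For a volume with slices $x_1,\dots,x_N$:

1. a slice encoder $E$ (vision transformer or 2D ResNet) maps each slice to
   a feature $f_i = E(x_i) \in \mathbb{R}^d$;
2. one pre-norm Transformer block over $[\mathrm{CLS}, f_1, \dots, f_N]$
   followed by an affine head on the CLS output gives the class logits;
3. saliency = (CLS attention over slices) × (per-slice patch attention),
   resized mass-preservingly to voxel resolution, summing to one.

A 3D ResNet (depths 18/34/50/101/152, inflated kernels) with
activation-times-gradient saliency is included as the conventional
reference, plus linear / average / positional-embedding aggregation
ablations, the preprocessing chain (resampling, contrast subtraction,
foreground- and mask-centred crops, reader-consensus masks, ordinal
malignancy labelling), a seeded synthetic-lesion generator with exact ground
truth, a training recipe (class-balanced sampling, AdamW, early stopping on
validation AUC), and evaluation machinery (Mann–Whitney AUC, fast DeLong
paired comparison, bootstrap CIs, stratified group-aware splits, automated
slice/lesion localization checks).

Constructed at full scale, the architectures audit to their conventional
sizes: ViT-S encoder 21.6M parameters, ViT-B 85.7M, slice-transformer
aggregator 0.89M (22.5M for the full small model), 3D ResNet-18/50/101 at
33.2M / 46.2M / 85.2M.

## Worked example

Everything below is desk-scale (tiny encoder, 16-slice 32×32 synthetic
volumes) and runs on one CPU in about two minutes. The printed output is
from an actual run.

```r
library(sliceformer)

# generate a seeded synthetic dataset and split it grouped/stratified
spec <- synthSpec()                      # 16 slices of 32 x 32, prevalence 0.5
cases <- generateDataset(spec, n = 120, seed = 42)
ds <- casesToDataset(cases)
split <- stratifiedGroupSplit(ds$labels, seed = 42)

# build a tiny slice transformer and train it
model <- buildMST(vitConfig("tiny", side = 32),
                  aggregatorConfig("transformer", embedDim = 64, nSlices = 16),
                  seed = 42)
take <- function(ids) lapply(ds, `[`, ids)
fit <- trainModel(model, take(split@trainIds), take(split@valIds),
                  trainConfig(lr = 1e-3, maxEpochs = 20, seed = 42))
fit$bestValAUC
#> [1] 0.9555556

# evaluate on the held-out test cases, including localization checks
r <- evaluateModel(fit$model, take(split@testIds), localization = TRUE)
r
#> EvalResult: AUC 0.972 +/- 0.033 (95% CI 0.889-1.000)
#>   slice-hit rate 0.92, lesion-hit rate 0.50
#>   confusion (rows truth, cols predicted):
#>      predicted
#> truth  0 1
#>     0 12 0
#>     1 12 0

# fused attention saliency for a positive test volume
idx <- split@testIds[ds$labels[split@testIds] == 1][1]
sal <- computeSaliency(fit$model, ds$volumes[[idx]])
sal
#> SaliencyVolume (attention_fusion): 16 x 32 x 32, peak at (3, 11, 12), mass 1
which.max(apply(sal@values, 1, sum))     # most attended slice
#> [1] 5
ds$lesionSlices[[idx]]                   # ground-truth lesion slices
#> [1] 2 3 4 5 6 7
```

Ranking converges before calibration at this small budget: the AUC is 0.97
and the attention lands on lesion slices in 92% of positive cases, while the
raw 0.5-threshold confusion matrix still predicts the majority class. Longer
training (see below) calibrates the probabilities as well.

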
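#' @include AllGenerics.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

# S3 configuration lists are stored in S4 "list" slots
setOldClass(c("vitConfig", "list"))
setOldClass(c("cnnConfig", "list"))
setOldClass(c("resnetConfig", "list"))
setOldClass(c("aggregatorConfig", "list"))
setOldClass(c("trainConfig", "list"))
setOldClass(c("synthSpec", "list"))

#' MedicalVolume: a 3D grayscale scalar volume
#'
#' Container for one 3D medical image: a scalar voxel array indexed
#' (slice, row, col), its physical spacing in millimetres per axis, and a
#' modality tag. All preprocessing and model operations consume and return
#' this class.
#'
#' @slot voxels 3D numeric array (slice, row, col); all values finite.
#' @slot spacing numeric length 3, millimetres per voxel along
#'   (slice, row, col); all entries positive.
#' @slot modality one of `"MR"`, `"CT"`, `"synthetic"`.
#'
#' @param voxels,spacing,modality see slots.
#' @return `MedicalVolume()` returns a validated object.
#' @examples
#' v <- MedicalVolume(array(rnorm(4 * 8 * 8), c(4, 8, 8)),
#'                    spacing = c(3, 0.7, 0.7), modality = "MR")
#' v
#' @aliases MedicalVolume
#' @export MedicalVolume
#' @exportClass MedicalVolume
.MedicalVolume <- setClass("MedicalVolume",
  representation(voxels = "array", spacing = "numeric", modality = "character"),
  prototype(spacing = c(1, 1, 1), modality = "synthetic"))

MedicalVolume <- function(voxels, spacing = c(1, 1, 1), modality = "synthetic") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  .MedicalVolume(voxels = voxels, spacing = as.numeric(spacing),
                 modality = modality)
}

setValidity("MedicalVolume", function(object) {
  if (length(dim(object@voxels)) != 3L) return("'voxels' must be a 3D array")
  if (any(dim(object@voxels) < 1L)) return("every axis must have length >= 1")
  if (!all(is.finite(object@voxels))) return("'voxels' must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("'spacing' must be 3 positive numbers")
  if (!object@modality %in% c("MR", "CT", "synthetic"))
    return("'modality' must be one of MR, CT, synthetic")
  TRUE
})

#' @rdname voxels
setMethod("voxels", "MedicalVolume", function(x) x@voxels)
#' @rdname voxels
setMethod("spacing", "MedicalVolume", function(x) x@spacing)
#' @rdname voxels
setMethod("modality", "MedicalVolume", function(x) x@modality)

setMethod("show", "MedicalVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("MedicalVolume: %d x %d x %d voxels (slice, row, col), %s\n",
              d[1], d[2], d[3], object@modality))
  cat(sprintf("  spacing (mm): %.3g x %.3g x %.3g | intensity range [%.4g, %.4g]\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              min(object@voxels), max(object@voxels)))
})

#' SynthCase: one synthetic volume with known lesion ground truth
#'
#' @slot volume a [MedicalVolume-class].
#' @slot label integer 0 (background only) or 1 (one lesion present).
#' @slot lesionSlices integer vector of 1-based slice indices intersected by
#'   the lesion; empty iff `label == 0`; contiguous when nonempty.
#' @slot lesionMask binary array congruent with the volume, nonzero only on
#'   `lesionSlices`.
#' @export
#' @exportClass SynthCase
SynthCase <- setClass("SynthCase",
  representation(volume = "MedicalVolume", label = "integer",
                 lesionSlices = "integer", lesionMask = "array"))

setValidity("SynthCase", function(object) {
  if (!object@label %in% c(0L, 1L)) return("'label' must be 0 or 1")
  if (!identical(dim(object@lesionMask), dim(object@volume@voxels)))
    return("'lesionMask' must be congruent with the volume")
  pos <- object@label == 1L
  if (pos && length(object@lesionSlices) == 0L)
    return("positive case must have nonempty lesionSlices")
  if (!pos && (length(object@lesionSlices) > 0L || any(object@lesionMask != 0)))
    return("negative case must have empty lesionSlices and an empty mask")
  if (pos) {
    if (any(diff(sort(object@lesionSlices)) != 1L))
      return("lesionSlices must be contiguous")
    off <- setdiff(seq_len(dim(object@lesionMask)[1]), object@lesionSlices)
    if (any(object@lesionMask[off, , ] != 0))
      return("mask must be zero off the lesion slices")
    if (sum(object@lesionMask != 0) < 1) return("positive case needs a nonempty mask")
  }
  TRUE
})

setMethod("show", "SynthCase", function(object) {
  cat(sprintf("SynthCase: label %d%s\n", object@label,
              if (object@label == 1L)
                sprintf(", lesion on slices %d-%d (%d voxels)",
                        min(object@lesionSlices), max(object@lesionSlices),
                        sum(object@lesionMask != 0)) else ""))
  show(object@volume)
})

#' AnnotationSet: multi-reader masks and malignancy ratings for one nodule
#'
#' @slot readerMasks list of 1-4 congruent binary arrays, one per reader.
#' @slot ratings numeric vector (one per reader) of ordinal malignancy
#'   ratings on the 1 ("highly unlikely") to 5 ("highly suspicious") scale.
#' @slot diameterMM nonnegative nodule diameter in millimetres.
#'
#' @param readerMasks,ratings,diameterMM see slots.
#' @export AnnotationSet
#' @exportClass AnnotationSet
.AnnotationSet <- setClass("AnnotationSet",
  representation(readerMasks = "list", ratings = "numeric", diameterMM = "numeric"),
  prototype(diameterMM = 0))

AnnotationSet <- function(readerMasks, ratings, diameterMM = 0) {
  .AnnotationSet(readerMasks = readerMasks, ratings = as.numeric(ratings),
                 diameterMM = as.numeric(diameterMM))
}

setValidity("AnnotationSet", function(object) {
  n <- length(object@readerMasks)
  if (n < 1L || n > 4L) return("between 1 and 4 reader masks required")
  d <- dim(object@readerMasks[[1]])
  for (m in object@readerMasks)
    if (!identical(dim(m), d)) return("reader masks must have congruent shapes")
  if (length(object@ratings) != n)
    return("one rating per reader required")
  if (any(object@ratings < 1 | object@ratings > 5))
    return("ratings must lie in [1, 5]")
  if (length(object@diameterMM) != 1L || object@diameterMM < 0)
    return("'diameterMM' must be a nonnegative scalar")
  TRUE
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d readers, ratings (%s), diameter %.1f mm\n",
              length(object@readerMasks), paste(object@ratings, collapse = ", "),
              object@diameterMM))
})

#' SliceFeatureSet: per-slice encoder outputs for one volume
#'
#' @slot features N x d matrix: one encoder feature vector per slice.
#' @slot patchMaps list of per-slice patch-attention grids (possibly empty
#'   for convolutional encoders), aligned with the rows of `features`.
#' @slot sliceIds integer slice identifiers, `0:(N-1)`.
#' @param features,patchMaps,sliceIds see slots.
#' @export SliceFeatureSet
#' @exportClass SliceFeatureSet
.SliceFeatureSet <- setClass("SliceFeatureSet",
  representation(features = "matrix", patchMaps = "list", sliceIds = "integer"))

SliceFeatureSet <- function(features, patchMaps = list(),
                            sliceIds = seq_len(nrow(features)) - 1L) {
  .SliceFeatureSet(features = features, patchMaps = patchMaps,
                   sliceIds = as.integer(sliceIds))
}

setValidity("SliceFeatureSet", function(object) {
  if (!all(is.finite(object@features))) return("features must be finite")
  if (length(object@sliceIds) != nrow(object@features))
    return("sliceIds must match the feature rows")
  if (length(object@patchMaps) > 0 &&
      length(object@patchMaps) != nrow(object@features))
    return("patchMaps must be empty or one per slice")
  TRUE
})

setMethod("show", "SliceFeatureSet", function(object) {
  cat(sprintf("SliceFeatureSet: %d slices x %d features%s\n",
              nrow(object@features), ncol(object@features),
              if (length(object@patchMaps)) ", with patch-attention maps"
              else ""))
})

#' SliceEncoding: one slice's feature vector and patch attention
#'
#' @slot feature numeric feature vector (the classification-token embedding
#'   for transformer encoders, the pooled 512-vector for the CNN encoder).
#' @slot patchAttention g x g matrix of nonnegative weights summing to one,
#'   or `NULL` for convolutional encoders.
#' @export
#' @exportClass SliceEncoding
SliceEncoding <- setClass("SliceEncoding",
  representation(feature = "numeric", patchAttention = "matrixOrNULL"))

setMethod("show", "SliceEncoding", function(object) {
  cat(sprintf("SliceEncoding: %d-dim feature%s\n", length(object@feature),
              if (is.null(object@patchAttention)) ""
              else sprintf(", %d x %d patch attention",
                           nrow(object@patchAttention),
                           ncol(object@patchAttention))))
})

#' ClassifierOutput: logits plus slice attention
#'
#' @slot logits numeric vector, one entry per class.
#' @slot sliceAttention nonnegative vector summing to one (transformer
#'   aggregators) or `NULL` (linear / average aggregators).
#' @export
#' @exportClass ClassifierOutput
ClassifierOutput <- setClass("ClassifierOutput",
  representation(logits = "numeric", sliceAttention = "numericOrNULL"))

setValidity("ClassifierOutput", function(object) {
  if (!all(is.finite(object@logits))) return("logits must be finite")
  if (!is.null(object@sliceAttention)) {
    if (any(object@sliceAttention < 0)) return("slice attention must be nonnegative")
    if (abs(sum(object@sliceAttention) - 1) > 1e-6)
      return("slice attention must sum to 1")
  }
  TRUE
})

setMethod("show", "ClassifierOutput", function(object) {
  cat("ClassifierOutput: logits",
      paste(sprintf("%.4f", object@logits), collapse = " "), "\n")
  if (!is.null(object@sliceAttention))
    cat(sprintf("  top attended slice %d (weight %.3f)\n",
                which.max(object@sliceAttention), max(object@sliceAttention)))
})

#' AttentionBundle: slice weights, patch maps, and the fused saliency volume
#'
#' The fused map satisfies `sum(combined[i, , ]) == sliceWeights[i]` per slice
#' and sums to one overall, so slice-level and within-slice attention can be
#' read off the same object.
#'
#' @slot sliceWeights length-N nonnegative vector summing to one.
#' @slot patchMaps list of N nonnegative g x g grids, each summing to one.
#' @slot combined N x H x W nonnegative array with total mass one.
#' @export
#' @exportClass AttentionBundle
AttentionBundle <- setClass("AttentionBundle",
  representation(sliceWeights = "numeric", patchMaps = "list", combined = "array"))

setValidity("AttentionBundle", function(object) {
  n <- length(object@sliceWeights)
  if (any(object@sliceWeights < 0) || abs(sum(object@sliceWeights) - 1) > 1e-6)
    return("slice weights must be nonnegative and sum to 1")
  if (length(object@patchMaps) != n) return("one patch map per slice required")
  for (m in object@patchMaps) {
    if (any(m < 0) || abs(sum(m) - 1) > 1e-6)
      return("each patch map must be nonnegative and sum to 1")
  }
  if (dim(object@combined)[1] != n) return("combined must have one plane per slice")
  if (any(object@combined < 0)) return("combined map must be nonnegative")
  if (abs(sum(object@combined) - 1) > 1e-5) return("combined map must sum to 1")
  perSlice <- apply(object@combined, 1, sum)
  if (any(abs(perSlice - object@sliceWeights) > 1e-5))
    return("per-slice mass must equal the slice weights")
  TRUE
})

setMethod("show", "AttentionBundle", function(object) {
  cat(sprintf("AttentionBundle: %d slices, fused map %s, top slice %d (weight %.3f)\n",
              length(object@sliceWeights),
              paste(dim(object@combined), collapse = " x "),
              which.max(object@sliceWeights), max(object@sliceWeights)))
})

#' SaliencyVolume: a nonnegative explainability map aligned to a volume
#'
#' @slot values nonnegative N x H x W array aligned with the model input.
#' @slot method `"attention_fusion"` (slice transformer) or `"gradcam3d"`
#'   (3D CNN activation-times-gradient).
#' @export
#' @exportClass SaliencyVolume
SaliencyVolume <- setClass("SaliencyVolume",
  representation(values = "array", method = "character"))

setValidity("SaliencyVolume", function(object) {
  if (length(dim(object@values)) != 3L) return("'values' must be a 3D array")
  if (any(object@values < 0)) return("saliency must be nonnegative")
  if (!object@method %in% c("attention_fusion", "gradcam3d"))
    return("unknown saliency method")
  TRUE
})

setMethod("show", "SaliencyVolume", function(object) {
  peak <- which(object@values == max(object@values), arr.ind = TRUE)[1, ]
  cat(sprintf("SaliencyVolume (%s): %s, peak at (%s), mass %.4g\n",
              object@method, paste(dim(object@values), collapse = " x "),
              paste(peak, collapse = ", "), sum(object@values)))
})

#' Split: a grouped, stratified train / validation / test partition
#'
#' @slot trainIds,valIds,testIds disjoint integer index vectors covering all
#'   samples.
#' @slot seed integer seed the split was drawn with.
#' @export
#' @exportClass Split
Split <- setClass("Split",
  representation(trainIds = "integer", valIds = "integer",
                 testIds = "integer", seed = "integer"))

setValidity("Split", function(object) {
  all3 <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(all3)) return("partitions must be disjoint")
  TRUE
})

setMethod("show", "Split", function(object) {
  cat(sprintf("Split: %d train / %d val / %d test (seed %d)\n",
              length(object@trainIds), length(object@valIds),
              length(object@testIds), object@seed))
})

#' EvalResult: AUC with uncertainty plus localization proxy rates
#'
#' @slot auc area under the ROC curve (Mann-Whitney concordance).
#' @slot aucSD bootstrap standard deviation of the AUC.
#' @slot ci95 percentile bootstrap 95% interval, `c(lo, hi)`.
#' @slot delongP two-sided DeLong p-value against a reference model's scores,
#'   or `NA` when no comparison was requested.
#' @slot confusion 2 x 2 count matrix at probability threshold 0.5
#'   (rows = truth 0/1, cols = predicted 0/1).
#' @slot sliceHitRate,lesionHitRate fractions of evaluated positive cases
#'   whose saliency argmax slice / peak voxel hit the lesion (NA if not
#'   evaluated).
#' @export
#' @exportClass EvalResult
EvalResult <- setClass("EvalResult",
  representation(auc = "numeric", aucSD = "numeric", ci95 = "numeric",
                 delongP = "numeric", confusion = "matrix",
                 sliceHitRate = "numeric", lesionHitRate = "numeric"),
  prototype(delongP = NA_real_, sliceHitRate = NA_real_, lesionHitRate = NA_real_))

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: AUC %.3f +/- %.3f (95%% CI %.3f-%.3f)\n",
              object@auc, object@aucSD, object@ci95[1], object@ci95[2]))
  if (!is.na(object@delongP))
    cat(sprintf("  DeLong p vs reference: %.4g\n", object@delongP))
  if (!is.na(object@sliceHitRate))
    cat(sprintf("  slice-hit rate %.2f, lesion-hit rate %.2f\n",
                object@sliceHitRate, object@lesionHitRate))
  cat("  confusion (rows truth, cols predicted):\n")
  print(object@confusion)
})

#' TrainHistory: per-epoch training record with early-stopping bookkeeping
#'
#' @slot epochs data.frame with columns `epoch`, `loss`, `valAUC`.
#' @slot bestEpoch epoch with the highest validation AUC.
#' @slot stoppedEpoch last epoch that ran.
#' @export
#' @exportClass TrainHistory
TrainHistory <- setClass("TrainHistory",
  representation(epochs = "data.frame", bestEpoch = "integer",
                 stoppedEpoch = "integer"))

setValidity("TrainHistory", function(object) {
  if (object@bestEpoch > object@stoppedEpoch)
    return("bestEpoch cannot exceed stoppedEpoch")
  TRUE
})

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf("TrainHistory: %d epochs, best epoch %d (val AUC %.3f)\n",
              object@stoppedEpoch, object@bestEpoch,
              object@epochs$valAUC[object@bestEpoch]))
})

# --- model classes -----------------------------------------------------------

#' ViTEncoder: a vision-transformer slice encoder
#'
#' Patch embedding, learned positional embeddings, a classification token,
#' optional register tokens, pre-norm Transformer blocks, and a final layer
#' norm. `encodeSlice` returns the classification-token embedding and the
#' classification token's patch-attention grid from the last block.
#'
#' @slot config list from [vitConfig()].
#' @slot params nested list of parameter arrays.
#' @export
#' @exportClass ViTEncoder
ViTEncoder <- setClass("ViTEncoder",
  representation(config = "list", params = "list"))

setMethod("show", "ViTEncoder", function(object) {
  cfg <- object@config
  cat(sprintf("ViTEncoder: side %d, patch %d, embed %d, depth %d, heads %d, registers %d%s\n",
              cfg$side, cfg$patch, cfg$embedDim, cfg$depth, cfg$heads,
              cfg$nRegisters, if (isTRUE(cfg$frozen)) " (frozen)" else ""))
  cat(sprintf("  %s trainable parameters\n",
              format(countParams(object), big.mark = ",")))
})

#' CNNEncoder: a 2D residual-network slice encoder
#'
#' The standard 2D residual network with its final linear layer removed; the
#' post-pooling feature vector (512 for depth 18/34) is the slice feature.
#' No patch-attention grid is produced.
#'
#' @slot config list from [cnnConfig()].
#' @slot params nested list of parameter arrays.
#' @slot state batch-norm running statistics.
#' @export
#' @exportClass CNNEncoder
CNNEncoder <- setClass("CNNEncoder",
  representation(config = "list", params = "list", state = "list"))

setMethod("show", "CNNEncoder", function(object) {
  cat(sprintf("CNNEncoder: 2D ResNet-%d feature extractor, %d-dim features, %s parameters\n",
              object@config$depth, object@config$embedDim,
              format(countParams(object), big.mark = ",")))
})

#' SliceAggregator: aggregates per-slice features into class logits
#'
#' Four kinds: `"transformer"` (classification token + one pre-norm encoder
#' layer; the reference architecture), `"transformer_adpe"` (adds a learned
#' additive positional embedding per slice index), `"linear"` (flatten all
#' slice features and apply one affine map), and `"average"` (mean feature
#' vector through an affine head).
#'
#' @slot config list from [aggregatorConfig()].
#' @slot params nested list of parameter arrays.
#' @export
#' @exportClass SliceAggregator
SliceAggregator <- setClass("SliceAggregator",
  representation(config = "list", params = "list"))

setMethod("show", "SliceAggregator", function(object) {
  cfg <- object@config
  cat(sprintf("SliceAggregator: kind %s, embed %d, heads %d, ffn %d, %d classes, %s parameters\n",
              cfg$kind, cfg$embedDim, cfg$heads %||% NA, cfg$ffnDim %||% NA,
              cfg$nClasses, format(countParams(object), big.mark = ",")))
})

#' MSTModel: slice encoder plus slice aggregator
#'
#' The full slice-transformer classifier: every slice of a volume is encoded
#' by the 2D encoder, the per-slice features are aggregated (by default
#' through a single-layer Transformer with a classification token), and an
#' affine head yields class logits. Attention flows out of both stages and is
#' fused into a volume-resolution saliency map by [computeSaliency()].
#'
#' @slot encoder a [ViTEncoder-class] or [CNNEncoder-class].
#' @slot aggregator a [SliceAggregator-class].
#' @export
#' @exportClass MSTModel
MSTModel <- setClass("MSTModel",
  representation(encoder = "ANY", aggregator = "SliceAggregator"))

setMethod("show", "MSTModel", function(object) {
  cat(sprintf("MSTModel (%s trainable parameters)\n",
              format(countParams(object), big.mark = ",")))
  show(object@encoder)
  show(object@aggregator)
})

#' ResNet3D: the 3D convolutional residual reference model
#'
#' Canonical residual network with every k x k kernel inflated to
#' k x k x k: a 7^3 stem convolution, max pooling, four down-sampling
#' residual stages (basic blocks for depth 18, bottlenecks for 50/101/152),
#' global average pooling, and an affine head.
#'
#' @slot config list from [resnetConfig()].
#' @slot params nested list of parameter arrays.
#' @slot state batch-norm running statistics.
#' @export
#' @exportClass ResNet3D
ResNet3D <- setClass("ResNet3D",
  representation(config = "list", params = "list", state = "list"))

setMethod("show", "ResNet3D", function(object) {
  cat(sprintf("ResNet3D: depth %d, %d classes, %s parameters (%.0f million)\n",
              object@config$depth, object@config$nClasses,
              format(countParams(object), big.mark = ","),
              round(countParams(object) / 1e6)))
})
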
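#' @include utils-internal.R
NULL

#' Accessors for volume objects
#'
#' `voxels` returns the raw 3D intensity array (slice, row, col), `spacing`
#' the physical voxel spacing in millimetres per axis, and `modality` the
#' modality tag (`"MR"`, `"CT"` or `"synthetic"`).
#'
#' @param x a [MedicalVolume-class] object.
#' @return `voxels`: a 3D array; `spacing`: numeric length 3; `modality`:
#'   character scalar.
#' @examples
#' v <- MedicalVolume(array(0, c(4, 8, 8)))
#' dim(voxels(v)); spacing(v); modality(v)
#' @aliases voxels spacing modality
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname voxels
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Count trainable parameters of a model or model configuration
#'
#' Returns the exact number of trainable scalar parameters. Works both on
#' constructed models (sums the element counts of every parameter array) and
#' on configuration objects (sums the declared parameter shapes without
#' allocating the arrays; the two routes agree by construction and are
#' cross-checked in the test suite).
#'
#' @param object a model (e.g. [MSTModel-class], [ResNet3D-class],
#'   [ViTEncoder-class], [SliceAggregator-class]) or a configuration list
#'   created by [vitConfig()], [cnnConfig()], [aggregatorConfig()] or
#'   [resnetConfig()].
#' @return integer-valued numeric: the exact parameter count. Use
#'   [paramsMillions()] for the conventional rounded-to-millions report.
#' @export
setGeneric("countParams", function(object) standardGeneric("countParams"))

#' Encode one 2D slice into a feature vector (and patch-attention grid)
#'
#' @param encoder a [ViTEncoder-class] or [CNNEncoder-class].
#' @param sliceImage a square numeric matrix (single-channel slice; it is
#'   replicated to the encoder's expected channel count internally).
#' @return a [SliceEncoding-class]: the classification-token feature vector
#'   and, for transformer encoders, the g x g patch-attention grid
#'   (nonnegative, summing to one).
#' @export
setGeneric("encodeSlice", function(encoder, sliceImage) standardGeneric("encodeSlice"))

#' Aggregate per-slice features and classify the volume
#'
#' @param aggregator a [SliceAggregator-class].
#' @param feats a [SliceFeatureSet-class] whose row count equals the
#'   aggregator's configured slice count (the `linear` kind is the only one
#'   that requires a fixed count; the transformer and average kinds accept
#'   any number of rows).
#' @return a [ClassifierOutput-class] with class logits and, for transformer
#'   kinds, the slice-attention vector (nonnegative, summing to one).
#' @export
setGeneric("aggregateAndClassify",
           function(aggregator, feats) standardGeneric("aggregateAndClassify"))

#' Forward a volume through a classification model
#'
#' @param model an [MSTModel-class] or [ResNet3D-class].
#' @param vol a [MedicalVolume-class] or 3D array (slice, row, col).
#' @param ... further arguments passed to methods.
#' @return a list with `logits` (length `nClasses`) plus, for the slice
#'   transformer, `sliceAttention` and per-slice `patchMaps`.
#' @export
setGeneric("predictVolume", function(model, vol, ...) standardGeneric("predictVolume"))

#' Compute an explainability map for a volume
#'
#' For the slice transformer this fuses slice attention with patch attention
#' ([combineAttention()]); for the 3D residual network it multiplies the last
#' convolutional stage's activations with the class-score gradients
#' ([gradCAM3D()]).
#'
#' @inheritParams predictVolume
#' @param classIndex 0-based class whose score is explained; defaults to the
#'   predicted class.
#' @param ... further arguments passed to methods.
#' @return a [SaliencyVolume-class] aligned with the input volume (and, for
#'   the transformer, the underlying [AttentionBundle-class] as attribute
#'   `"bundle"`).
#' @export
setGeneric("computeSaliency",
           function(model, vol, classIndex = NULL, ...) standardGeneric("computeSaliency"))
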
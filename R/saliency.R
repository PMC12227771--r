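# Explainability: classification-token attention extraction, fusion of slice
# and patch attention into a volume-resolution map, and the
# activation-times-gradient map for the 3D CNN reference.

#' Extract normalized classification-token attention
#'
#' Given one row of classification-token attention per head, drops the
#' classification / register columns, renormalizes each head's remaining
#' weights to sum to one, and averages across heads. The result is a
#' nonnegative vector summing to one.
#'
#' @param attnRows heads x tokens matrix: the classification-token attention
#'   row of every head.
#' @param dropCols column indices of the classification and register tokens
#'   to exclude from the map.
#' @return numeric vector over the remaining (content) tokens, summing to 1.
#' @examples
#' extractClsAttention(matrix(c(2, 3, 5), 1), dropCols = integer(0))
#' @export
extractClsAttention <- function(attnRows, dropCols = integer(0)) {
  if (is.null(dim(attnRows))) attnRows <- matrix(attnRows, 1)
  if (length(dropCols) > 0)
    attnRows <- attnRows[, -dropCols, drop = FALSE]
  if (any(attnRows < 0)) stop("attention weights must be nonnegative")
  s <- rowSums(attnRows)
  if (any(s <= 0)) stop("degenerate attention: a head has zero total weight ",
                        "over the content tokens")
  colMeans(attnRows / s)
}

# resize a nonnegative map with separable linear interpolation, then
# renormalize so interpolation preserves the map's total mass
resizeNormalized <- function(m, outDim) {
  r <- resizeLinear(m, outDim)
  r[r < 0] <- 0
  s <- sum(r)
  if (s > 0) r <- r / s
  r
}

#' Fuse slice attention with per-slice patch attention
#'
#' Each slice's patch map is bilinearly interpolated to the in-plane input
#' size, renormalized to unit mass (so interpolation does not change how much
#' attention a slice carries), and scaled by that slice's attention weight.
#' The fused volume therefore sums to one overall, with per-slice mass equal
#' to the slice weights.
#'
#' @param sliceWeights nonnegative length-N vector summing to one.
#' @param patchMaps list of N nonnegative g x g matrices, each summing to
#'   one.
#' @param outHW integer length 2: in-plane output size `(H, W)`.
#' @return an [AttentionBundle-class].
#' @export
combineAttention <- function(sliceWeights, patchMaps, outHW) {
  n <- length(sliceWeights)
  if (length(patchMaps) != n)
    stop("length mismatch: ", n, " slice weights but ", length(patchMaps),
         " patch maps")
  if (any(sliceWeights < 0) || abs(sum(sliceWeights) - 1) > 1e-6)
    stop("slice weights must be nonnegative and sum to 1")
  combined <- array(0, c(n, outHW[1], outHW[2]))
  for (i in seq_len(n)) {
    m <- patchMaps[[i]]
    if (any(m < 0) || abs(sum(m) - 1) > 1e-6)
      stop("patch map ", i, " must be nonnegative and sum to 1")
    combined[i, , ] <- sliceWeights[i] * resizeNormalized(m, outHW)
  }
  AttentionBundle(sliceWeights = as.numeric(sliceWeights),
                  patchMaps = patchMaps, combined = combined)
}

#' Activation-times-gradient saliency for 3D CNNs
#'
#' Multiplies the last convolutional stage's activations elementwise with the
#' class-score gradients, sums over channels, clips negative values to zero,
#' and trilinearly interpolates to the requested output shape. (The canonical
#' channel-pooled variant, which first averages the gradients spatially into
#' per-channel weights, is available via `pooled = TRUE`.)
#'
#' @param activations,gradients congruent arrays `(d, h, w, C)` (or
#'   `(d, h, w)` for a single channel) from the hooked last convolutional
#'   stage.
#' @param outShape optional integer length 3 output shape; if `NULL` the map
#'   stays at activation resolution.
#' @param pooled use the channel-pooled weighting instead of the elementwise
#'   product.
#' @return a [SaliencyVolume-class] with `method = "gradcam3d"`.
#' @export
gradCAM3D <- function(activations, gradients, outShape = NULL, pooled = FALSE) {
  if (length(dim(activations)) == 3L)
    activations <- array(activations, c(dim(activations), 1L))
  if (length(dim(gradients)) == 3L)
    gradients <- array(gradients, c(dim(gradients), 1L))
  if (!identical(dim(activations), dim(gradients)))
    stop("shape mismatch: activations ",
         paste(dim(activations), collapse = "x"), " vs gradients ",
         paste(dim(gradients), collapse = "x"))
  d <- dim(activations)
  pr <- if (pooled) {
    w <- apply(gradients, 4, mean)
    sweep(activations, 4, w, `*`)
  } else {
    activations * gradients
  }
  m <- array(rowSums(pr, dims = 3), d[1:3])
  m[m < 0] <- 0
  if (!is.null(outShape)) m <- pmax(resizeLinear(m, as.integer(outShape)), 0)
  SaliencyVolume(values = m, method = "gradcam3d")
}

#' @describeIn computeSaliency slice transformer: fuse the slice-attention
#'   weights with the per-slice patch-attention grids
#'   (`method = "attention_fusion"`); the underlying [AttentionBundle-class]
#'   is attached as attribute `"bundle"`. `classIndex` is ignored - the
#'   attention flow is not class-conditional.
setMethod("computeSaliency", "MSTModel", function(model, vol, classIndex = NULL, ...) {
  a <- if (is(vol, "MedicalVolume")) voxels(vol) else vol
  pred <- predictVolume(model, vol)
  if (is.null(pred$sliceAttention))
    stop("attention saliency requires a transformer aggregator")
  bundle <- combineAttention(pred$sliceAttention, pred$patchMaps, dim(a)[2:3])
  out <- SaliencyVolume(values = bundle@combined, method = "attention_fusion")
  attr(out, "bundle") <- bundle
  out
})

#' Write a saliency map as NIfTI aligned to its input volume
#'
#' @param sal a [SaliencyVolume-class].
#' @param path output path.
#' @param spacing voxel spacing of the aligned input volume.
#' @return the path, invisibly.
#' @export
writeSaliency <- function(sal, path, spacing = c(1, 1, 1)) {
  writeVolume(MedicalVolume(sal@values, spacing = spacing), path)
}
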
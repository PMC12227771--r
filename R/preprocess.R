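# Volume-level preparation (grid resampling, contrast subtraction, crops) and
# annotation-derivation rules (multi-reader consensus masks, ordinal
# malignancy labelling with a minimum-size filter).

#' LabelDecision: outcome of the nodule-labelling rules
#'
#' @slot verdict `"benign"`, `"malignant"` or `"excluded"`.
#' @slot reason `"ok"` for labelled nodules, `"small_nodule"` for nodules
#'   below the diameter filter, `"ambiguous_rating"` for a mean rating of
#'   exactly 3.
#' @export
#' @exportClass LabelDecision
LabelDecision <- setClass("LabelDecision",
  representation(verdict = "character", reason = "character"))

setValidity("LabelDecision", function(object) {
  if (!object@verdict %in% c("benign", "malignant", "excluded"))
    return("unknown verdict")
  if (!object@reason %in% c("ok", "small_nodule", "ambiguous_rating"))
    return("unknown reason")
  if ((object@verdict == "excluded") != (object@reason != "ok"))
    return("verdict 'excluded' iff reason != 'ok'")
  TRUE
})

setMethod("show", "LabelDecision", function(object) {
  cat(sprintf("LabelDecision: %s (%s)\n", object@verdict, object@reason))
})

#' Resample a volume to a target physical spacing
#'
#' Linear interpolation on the voxel-centre grid; the physical extent
#' `(n - 1) * spacing` per axis is preserved to within one voxel. The typical
#' use is standardizing breast MRI to 0.7 x 0.7 mm in-plane and 3.0 mm
#' between slices.
#'
#' @param vol a [MedicalVolume-class].
#' @param targetSpacing numeric length 3, millimetres per voxel
#'   (slice, row, col); all positive.
#' @return a [MedicalVolume-class] with `spacing == targetSpacing`.
#' @examples
#' v <- MedicalVolume(array(rnorm(8 * 16 * 16), c(8, 16, 16)),
#'                    spacing = c(3, 1.4, 1.4))
#' dim(voxels(resampleVolume(v, c(3, 0.7, 0.7))))
#' @export
resampleVolume <- function(vol, targetSpacing) {
  targetSpacing <- as.numeric(targetSpacing)
  if (length(targetSpacing) != 3L || any(!is.finite(targetSpacing)) ||
      any(targetSpacing <= 0))
    stop("targetSpacing must be 3 positive numbers")
  a <- voxels(vol)
  if (!all(is.finite(a))) stop("input volume contains non-finite values")
  sp <- spacing(vol)
  for (ax in 1:3) {
    if (targetSpacing[ax] == sp[ax]) next
    n <- dim(a)[ax]
    extent <- (n - 1) * sp[ax]
    nOut <- floor(extent / targetSpacing[ax] + 1e-9) + 1L
    pos <- (seq_len(nOut) - 1) * targetSpacing[ax] / sp[ax]
    a <- interpAxis(a, ax, pos)
  }
  MedicalVolume(a, spacing = targetSpacing, modality = modality(vol))
}

#' Contrast-subtraction image
#'
#' Voxelwise difference of a pre/post-contrast pair, without clamping. The
#' default direction `post - pre` makes contrast enhancement positive, which
#' is the clinically intended subtraction image; set
#' `direction = "pre_minus_post"` for the opposite sign convention.
#'
#' @param pre,post congruent [MedicalVolume-class] objects (same shape and
#'   spacing).
#' @param direction `"post_minus_pre"` (default) or `"pre_minus_post"`.
#' @return a [MedicalVolume-class] carrying the pre-volume's spacing and
#'   modality.
#' @export
makeSubtraction <- function(pre, post, direction = c("post_minus_pre", "pre_minus_post")) {
  direction <- match.arg(direction)
  if (!identical(dim(voxels(pre)), dim(voxels(post))))
    stop("shape mismatch: pre is ", paste(dim(voxels(pre)), collapse = "x"),
         ", post is ", paste(dim(voxels(post)), collapse = "x"))
  if (any(abs(spacing(pre) - spacing(post)) > 1e-9))
    stop("pre and post volumes must share the same spacing")
  d <- if (direction == "post_minus_pre") voxels(post) - voxels(pre)
       else voxels(pre) - voxels(post)
  MedicalVolume(d, spacing = spacing(pre), modality = modality(pre))
}

# 1-based half-open crop window of length `out` centred at `centre`, clipped
# to stay inside 1..n (assumes out <= n).
cropStart <- function(n, out, centre) {
  start <- round(centre) - floor(out / 2)
  min(max(start, 1L), n - out + 1L)
}

# Pad an array symmetrically with `value` so every axis reaches at least
# `minDim`; returns the padded array and the index offset added per axis.
padTo <- function(a, minDim, value) {
  d <- dim(a)
  need <- pmax(minDim - d, 0L)
  before <- need %/% 2L
  if (all(need == 0L)) return(list(a = a, offset = c(0L, 0L, 0L)))
  out <- array(value, d + need)
  out[before[1] + seq_len(d[1]), before[2] + seq_len(d[2]),
      before[3] + seq_len(d[3])] <- a
  list(a = out, offset = as.integer(before))
}

#' Crop in-plane around the foreground centroid
#'
#' The foreground is defined as the voxels strictly above the
#' `thresholdPct`-th intensity percentile; the crop window of
#' `outRows x outCols` is centred on the rounded in-plane centroid of the
#' foreground, clipped to stay inside the image (padded with the volume
#' minimum when the requested window is larger than the image). The slice
#' axis is untouched. A constant-intensity volume has no strict-threshold
#' foreground and falls back to the geometric image centre.
#'
#' @param vol a [MedicalVolume-class].
#' @param outRows,outCols output in-plane size.
#' @param thresholdPct percentile (0-100) defining the foreground threshold;
#'   default 90.
#' @return the cropped [MedicalVolume-class].
#' @export
foregroundCenterCrop <- function(vol, outRows, outCols, thresholdPct = 90) {
  a <- voxels(vol)
  if (length(a) == 0) stop("empty volume")
  thr <- stats::quantile(a, thresholdPct / 100, names = FALSE)
  fg <- which(a > thr, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    centre <- c((dim(a)[2] + 1) / 2, (dim(a)[3] + 1) / 2)
  } else {
    centre <- c(mean(fg[, 2]), mean(fg[, 3]))
  }
  pad <- padTo(a, c(dim(a)[1], outRows, outCols), min(a))
  a <- pad$a
  centre <- centre + pad$offset[2:3]
  r0 <- cropStart(dim(a)[2], outRows, centre[1])
  c0 <- cropStart(dim(a)[3], outCols, centre[2])
  MedicalVolume(a[, r0 + seq_len(outRows) - 1L, c0 + seq_len(outCols) - 1L,
                  drop = FALSE],
                spacing = spacing(vol), modality = modality(vol))
}

#' Fixed-size spatial crop (center or seeded random)
#'
#' Inputs smaller than the requested shape are first padded symmetrically
#' with the volume minimum. Center mode uses offset `floor((in - out) / 2)`
#' per axis; random mode draws offsets uniformly over all valid positions
#' under the given seed. Random crops are the training-time counterpart of
#' the deterministic inference-time center crop.
#'
#' @param vol a [MedicalVolume-class].
#' @param outShape integer length 3 (slice, row, col).
#' @param mode `"center"` or `"random"`.
#' @param seed seed for random mode.
#' @return the cropped [MedicalVolume-class].
#' @export
spatialCrop <- function(vol, outShape, mode = c("center", "random"), seed = 1L) {
  mode <- match.arg(mode)
  outShape <- as.integer(outShape)
  pad <- padTo(voxels(vol), outShape, min(voxels(vol)))
  a <- pad$a
  d <- dim(a)
  off <- if (mode == "center") (d - outShape) %/% 2L
         else withSeed(seed, vapply(d - outShape, function(m)
           sample.int(m + 1L, 1L) - 1L, integer(1)))
  MedicalVolume(a[off[1] + seq_len(outShape[1]),
                  off[2] + seq_len(outShape[2]),
                  off[3] + seq_len(outShape[3]), drop = FALSE],
                spacing = spacing(vol), modality = modality(vol))
}

#' Crop a fixed window centred on a segmentation mask
#'
#' The window is centred on the mask's bounding-box centre, shifted to stay
#' inside the array, and padded symmetrically with the volume minimum when
#' the requested shape exceeds the volume. Used to extract nodule-centred
#' blocks from annotated scans.
#'
#' @param vol a [MedicalVolume-class].
#' @param mask binary array congruent with `vol`, nonempty.
#' @param outShape integer length 3 (slice, row, col).
#' @return the cropped [MedicalVolume-class].
#' @export
cropAroundMask <- function(vol, mask, outShape) {
  if (!identical(dim(mask), dim(voxels(vol))))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match volume shape ",
         paste(dim(voxels(vol)), collapse = "x"))
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  outShape <- as.integer(outShape)
  centre <- (apply(idx, 2, min) + apply(idx, 2, max)) / 2
  pad <- padTo(voxels(vol), outShape, min(voxels(vol)))
  a <- pad$a
  centre <- centre + pad$offset
  starts <- vapply(1:3, function(ax) cropStart(dim(a)[ax], outShape[ax], centre[ax]),
                   integer(1) * 1)
  MedicalVolume(a[starts[1] + seq_len(outShape[1]) - 1L,
                  starts[2] + seq_len(outShape[2]) - 1L,
                  starts[3] + seq_len(outShape[3]) - 1L, drop = FALSE],
                spacing = spacing(vol), modality = modality(vol))
}

#' Multi-reader consensus mask
#'
#' A voxel belongs to the consensus segmentation iff at least `minReaders`
#' readers marked it. The default of 2 (of up to 4) reproduces the >= 50%
#' consensus rule commonly used for multi-reader nodule outlines. With
#' `minReaders = 1` the consensus is the union of the reader masks; with
#' `minReaders` equal to the number of readers it is their intersection, and
#' raising `minReaders` never adds voxels.
#'
#' @param ann an [AnnotationSet-class] or a plain list of congruent binary
#'   arrays.
#' @param minReaders minimum number of agreeing readers (default 2).
#' @return a binary array of the readers' common shape.
#' @export
consensusMask <- function(ann, minReaders = 2L) {
  masks <- if (is(ann, "AnnotationSet")) ann@readerMasks else ann
  if (length(masks) < minReaders)
    stop("need at least ", minReaders, " reader masks, got ", length(masks))
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d))
    stop("incongruent reader mask shapes: ", paste(dim(m), collapse = "x"),
         " vs ", paste(d, collapse = "x"))
  counts <- Reduce(`+`, lapply(masks, function(m) (m != 0) * 1))
  out <- (counts >= minReaders) * 1
  array(out, d)
}

#' Derive a benign/malignant label from multi-reader ratings
#'
#' Nodules smaller than `minDiameterMM` are excluded (`small_nodule`);
#' otherwise the mean of the readers' 1-5 malignancy ratings decides: mean
#' above 3 is malignant, below 3 benign, exactly 3 excluded
#' (`ambiguous_rating`). Every valid input receives exactly one verdict.
#'
#' @param ann an [AnnotationSet-class].
#' @param minDiameterMM minimum nodule diameter in millimetres (default 3).
#' @return a [LabelDecision-class].
#' @examples
#' m <- array(1, c(2, 2, 2))
#' deriveNoduleLabel(AnnotationSet(list(m, m, m, m), c(4, 4, 5, 5), 10))
#' @export
deriveNoduleLabel <- function(ann, minDiameterMM = 3) {
  stopifnot(is(ann, "AnnotationSet"))
  if (length(ann@ratings) == 0) stop("ratings must be nonempty")
  if (any(ann@ratings < 1 | ann@ratings > 5))
    stop("ratings outside [1, 5]: ", paste(ann@ratings, collapse = ", "))
  if (ann@diameterMM < minDiameterMM)
    return(LabelDecision(verdict = "excluded", reason = "small_nodule"))
  m <- mean(ann@ratings)
  if (m > 3) LabelDecision(verdict = "malignant", reason = "ok")
  else if (m < 3) LabelDecision(verdict = "benign", reason = "ok")
  else LabelDecision(verdict = "excluded", reason = "ambiguous_rating")
}
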
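# Seeded synthetic volumes with known lesion ground truth. These emulate the
# kind of binary classification/localization task the package targets: a
# hyperintense ellipsoidal lesion spanning a contiguous slab of slices on a
# constant background with i.i.d. Gaussian noise (positives) versus
# background-only volumes (negatives), plus pre/post-contrast pairs and
# multi-reader annotation sets with controllable disagreement.

#' Specification of the synthetic-volume generator
#'
#' The defaults define the package's reference study conditions: 16 slices of
#' 32 x 32 pixels, one lesion in half of the cases, lesion contrast of 5
#' intensity units over a zero background with noise SD 0.5 (an "easy",
#' clearly separable setting), in-plane lesion radii of 4-8 pixels and a
#' lesion slab of 3-6 slices.
#'
#' @param nSlices,height,width volume shape (slice, row, col); `nSlices >= 4`.
#' @param lesionPrevalence probability in `[0, 1]` that a case is positive.
#' @param lesionIntensityDelta intensity added inside the lesion (arbitrary
#'   units).
#' @param lesionRadiusRange length-2 range (pixels) the in-plane ellipsoid
#'   semi-axes are drawn from, uniformly.
#' @param lesionSlabRange length-2 integer range (slices) of the lesion's
#'   slice extent; its maximum must not exceed `nSlices`.
#' @param noiseSD standard deviation of the additive Gaussian noise
#'   (intensity units, `>= 0`).
#' @param background constant background intensity.
#' @param spacing physical voxel spacing in mm (slice, row, col).
#' @return a validated list of class `"synthSpec"`.
#' @examples
#' sp <- synthSpec()
#' case <- generateCase(sp, seed = 7)
#' case
#' @export
synthSpec <- function(nSlices = 16L, height = 32L, width = 32L,
                      lesionPrevalence = 0.5, lesionIntensityDelta = 5,
                      lesionRadiusRange = c(4, 8), lesionSlabRange = c(3L, 6L),
                      noiseSD = 0.5, background = 0, spacing = c(3, 0.7, 0.7)) {
  spec <- list(nSlices = as.integer(nSlices), height = as.integer(height),
               width = as.integer(width),
               lesionPrevalence = lesionPrevalence,
               lesionIntensityDelta = lesionIntensityDelta,
               lesionRadiusRange = as.numeric(lesionRadiusRange),
               lesionSlabRange = as.integer(lesionSlabRange),
               noiseSD = noiseSD, background = background,
               spacing = as.numeric(spacing))
  validateSynthSpec(spec)
  class(spec) <- c("synthSpec", "list")
  spec
}

validateSynthSpec <- function(spec) {
  if (spec$nSlices < 4L)
    stop("invalid synthetic spec: nSlices must be >= 4, got ", spec$nSlices)
  if (spec$height < 4L || spec$width < 4L)
    stop("invalid synthetic spec: height and width must be >= 4, got ",
         spec$height, " x ", spec$width)
  if (spec$lesionPrevalence < 0 || spec$lesionPrevalence > 1)
    stop("lesionPrevalence must lie in [0, 1]")
  if (spec$noiseSD < 0) stop("noiseSD must be >= 0")
  if (length(spec$lesionSlabRange) != 2L ||
      max(spec$lesionSlabRange) > spec$nSlices)
    stop("lesionSlabRange maximum (", max(spec$lesionSlabRange),
         ") must not exceed nSlices (", spec$nSlices, ")")
  if (length(spec$lesionRadiusRange) != 2L || min(spec$lesionRadiusRange) < 1)
    stop("lesionRadiusRange must be a length-2 range with minimum >= 1")
  invisible(TRUE)
}

# Draw lesion geometry from the current RNG stream: ellipsoid centre, in-plane
# semi-axes, and slice semi-axis (half the slab extent). Returns the binary
# mask and the contiguous slice range it occupies.
drawLesion <- function(spec) {
  slab <- if (spec$lesionSlabRange[1] == spec$lesionSlabRange[2])
    spec$lesionSlabRange[1] else
    sample(spec$lesionSlabRange[1]:spec$lesionSlabRange[2], 1L)
  aS <- slab / 2
  aR <- stats::runif(1, spec$lesionRadiusRange[1], spec$lesionRadiusRange[2])
  aC <- stats::runif(1, spec$lesionRadiusRange[1], spec$lesionRadiusRange[2])
  # keep the ellipsoid inside the volume (midpoint when it barely fits)
  centreIn <- function(n, a) if (1 + a < n - a) stats::runif(1, 1 + a, n - a) else (1 + n) / 2
  cS <- centreIn(spec$nSlices, aS)
  cR <- centreIn(spec$height, aR)
  cC <- centreIn(spec$width, aC)
  s2 <- ((seq_len(spec$nSlices) - cS) / aS)^2
  r2 <- ((seq_len(spec$height) - cR) / aR)^2
  c2 <- ((seq_len(spec$width) - cC) / aC)^2
  mask <- outer(outer(s2, r2, `+`), c2, `+`) <= 1
  storage.mode(mask) <- "double"
  sl <- which(apply(mask, 1, sum) > 0)
  list(mask = mask, slices = as.integer(sl))
}

#' Generate one seeded synthetic case
#'
#' Deterministic for fixed `(spec, seed)`. A positive case contains exactly
#' one axis-aligned ellipsoid of intensity `background + lesionIntensityDelta`
#' spanning a contiguous slab of slices; a negative case is background plus
#' noise only.
#'
#' @param spec a [synthSpec()].
#' @param seed integer seed.
#' @return a [SynthCase-class].
#' @export
generateCase <- function(spec, seed) {
  validateSynthSpec(spec)
  withSeed(seed, {
    label <- stats::rbinom(1L, 1L, spec$lesionPrevalence)
    d <- c(spec$nSlices, spec$height, spec$width)
    mask <- array(0, d)
    slices <- integer(0)
    if (label == 1L) {
      les <- drawLesion(spec)
      mask <- les$mask
      slices <- les$slices
    }
    noise <- if (spec$noiseSD > 0)
      array(stats::rnorm(prod(d), 0, spec$noiseSD), d) else array(0, d)
    vox <- spec$background + spec$lesionIntensityDelta * mask + noise
    new("SynthCase",
        volume = MedicalVolume(vox, spacing = spec$spacing, modality = "synthetic"),
        label = as.integer(label), lesionSlices = slices, lesionMask = mask)
  })
}

#' Generate a seeded pre/post-contrast volume pair
#'
#' The post-contrast volume equals the pre-contrast volume plus
#' `lesionIntensityDelta` on the enhancing region plus independent noise, so
#' the subtraction image ([makeSubtraction()]) recovers the enhancement.
#'
#' @inheritParams generateCase
#' @return a list with `pre` and `post` ([MedicalVolume-class]) and the binary
#'   `truthMask` of the enhancing region (all-zero for a negative draw).
#' @export
generateContrastPair <- function(spec, seed) {
  validateSynthSpec(spec)
  withSeed(seed, {
    label <- stats::rbinom(1L, 1L, spec$lesionPrevalence)
    d <- c(spec$nSlices, spec$height, spec$width)
    mask <- if (label == 1L) drawLesion(spec)$mask else array(0, d)
    noise <- function() if (spec$noiseSD > 0)
      array(stats::rnorm(prod(d), 0, spec$noiseSD), d) else array(0, d)
    pre <- spec$background + noise()
    post <- pre + spec$lesionIntensityDelta * mask + noise()
    list(pre = MedicalVolume(pre, spacing = spec$spacing, modality = "synthetic"),
         post = MedicalVolume(post, spacing = spec$spacing, modality = "synthetic"),
         truthMask = mask)
  })
}

# Boundary voxels of a binary mask: voxels whose value differs from at least
# one 6-neighbour (both the inner rim of the mask and the outer rim of the
# background).
maskBoundary <- function(mask) {
  d <- dim(mask)
  m <- mask != 0
  diffNb <- array(FALSE, d)
  for (ax in 1:3) for (dlt in c(-1L, 1L)) {
    idx <- pmin(pmax(seq_len(d[ax]) + dlt, 1L), d[ax])
    nb <- switch(ax, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
                 m[, , idx, drop = FALSE])
    diffNb <- diffNb | (nb != m)
  }
  which(diffNb)
}

#' Generate a seeded multi-reader annotation set
#'
#' Each reader's mask is the true mask with an independent, seeded fraction
#' (`disagreement`) of its boundary voxels toggled; each reader's malignancy
#' rating is `ratingsCenter` plus Gaussian jitter, rounded and clamped to the
#' 1-5 scale. The RNG is consumed reader by reader: first the boundary
#' toggles (one uniform draw per boundary voxel), then the rating draw.
#'
#' @param trueMask binary 3D array, the consensus ground truth.
#' @param ratingsCenter real in `[1, 5]` the ratings are jittered around.
#' @param disagreement fraction in `[0, 1]` of boundary voxels toggled per
#'   reader.
#' @param nReaders number of readers (default 4).
#' @param ratingJitter standard deviation of the rating jitter (defaults to
#'   `disagreement`, so zero disagreement gives identical ratings).
#' @param seed integer seed.
#' @param diameterMM nodule diameter recorded in the annotation set; defaults
#'   to the largest in-plane extent of `trueMask` in voxels (unit spacing).
#' @return an [AnnotationSet-class].
#' @export
generateMultireader <- function(trueMask, ratingsCenter, disagreement,
                                nReaders = 4L, ratingJitter = disagreement,
                                seed = 1L, diameterMM = NULL) {
  if (nReaders < 1L) stop("nReaders must be >= 1, got ", nReaders)
  if (disagreement < 0 || disagreement > 1)
    stop("disagreement must lie in [0, 1]")
  if (ratingsCenter < 1 || ratingsCenter > 5)
    stop("ratingsCenter must lie in [1, 5]")
  if (!all(trueMask %in% c(0, 1))) stop("trueMask must be binary")
  if (is.null(diameterMM)) {
    idx <- which(trueMask != 0, arr.ind = TRUE)
    diameterMM <- if (nrow(idx) == 0) 0 else
      max(diff(range(idx[, 2])), diff(range(idx[, 3]))) + 1
  }
  boundary <- maskBoundary(trueMask)
  withSeed(seed, {
    masks <- vector("list", nReaders)
    ratings <- numeric(nReaders)
    for (r in seq_len(nReaders)) {
      m <- trueMask
      if (length(boundary) > 0) {
        toggle <- boundary[stats::runif(length(boundary)) < disagreement]
        m[toggle] <- 1 - m[toggle]
      }
      masks[[r]] <- m
      ratings[r] <- min(5, max(1, round(ratingsCenter +
                                          stats::rnorm(1, 0, ratingJitter))))
    }
    AnnotationSet(readerMasks = masks, ratings = ratings, diameterMM = diameterMM)
  })
}

#' Generate a reproducible set of synthetic cases
#'
#' @inheritParams generateCase
#' @param n number of cases.
#' @return a list of [SynthCase-class]; per-case seeds are derived from
#'   `seed`, so the whole set is reproducible and individual cases can be
#'   regenerated.
#' @export
generateDataset <- function(spec, n, seed) {
  caseSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(caseSeeds, function(s) generateCase(spec, s))
}

#' Write synthetic cases as NIfTI volumes with a metadata table
#'
#' Writes `case_<i>.nii.gz` and (for positives) `case_<i>_mask.nii.gz` plus a
#' `metadata.csv` with columns `case_id`, `label`, `lesion_slice_start`,
#' `lesion_slice_end`, `volume_path`, `mask_path`.
#'
#' @param cases list of [SynthCase-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the metadata data.frame.
#' @export
writeCases <- function(cases, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(cases), function(i) {
    case <- cases[[i]]
    id <- sprintf("case_%04d", i)
    vp <- file.path(dir, paste0(id, ".nii.gz"))
    writeVolume(case@volume, vp)
    mp <- NA_character_
    if (case@label == 1L) {
      mp <- file.path(dir, paste0(id, "_mask.nii.gz"))
      writeVolume(MedicalVolume(case@lesionMask, spacing = spacing(case@volume)), mp)
    }
    data.frame(case_id = id, label = case@label,
               lesion_slice_start = if (case@label == 1L) min(case@lesionSlices) else NA,
               lesion_slice_end = if (case@label == 1L) max(case@lesionSlices) else NA,
               volume_path = vp, mask_path = mp, stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti keeping the package's (slice, row, col) axis
#' order and spacing metadata.
#'
#' @param vol a [MedicalVolume-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag to stamp on the volume read back.
#' @return `readVolume` returns a [MedicalVolume-class]; `writeVolume` the
#'   path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(voxels(vol))
  RNifti::pixdim(img) <- spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, modality = "synthetic") {
  img <- RNifti::readNifti(path)
  MedicalVolume(array(as.numeric(img), dim(img)),
                spacing = RNifti::pixdim(img)[seq_len(3)], modality = modality)
}
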
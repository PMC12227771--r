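vol3 <- function(a, spacing = c(1, 1, 1)) MedicalVolume(a, spacing = spacing)

test_that("resampling to the input spacing is the identity", {
  set.seed(1)
  v <- vol3(array(rnorm(4 * 6 * 6), c(4, 6, 6)), spacing = c(3, 0.7, 0.7))
  out <- resampleVolume(v, c(3, 0.7, 0.7))
  expect_identical(voxels(out), voxels(v))
})

test_that("resampling a constant volume returns the same constant", {
  v <- vol3(array(2.5, c(4, 8, 8)), spacing = c(2, 1, 1))
  out <- resampleVolume(v, c(1, 0.4, 0.7))
  expect_true(all(abs(voxels(out) - 2.5) < 1e-12))
  expect_identical(spacing(out), c(1, 0.4, 0.7))
})

test_that("halving the spacing of a ramp inserts the exact midpoints", {
  # closed-form linear interpolation oracle on a 1D ramp 0,1,2,3
  v <- vol3(array(0:3, c(1, 1, 4)))
  out <- resampleVolume(v, c(1, 1, 0.5))
  expect_equal(as.vector(voxels(out)), seq(0, 3, by = 0.5), tolerance = 1e-12)
})

test_that("resampling preserves physical extent within one voxel", {
  v <- vol3(array(rnorm(5 * 10 * 8), c(5, 10, 8)), spacing = c(2, 1.5, 1.1))
  tgt <- c(0.9, 0.6, 0.8)
  out <- resampleVolume(v, tgt)
  inExt <- (dim(voxels(v)) - 1) * spacing(v)
  outExt <- (dim(voxels(out)) - 1) * tgt
  expect_true(all(abs(inExt - outExt) <= tgt))
})

test_that("resampling rejects non-finite volumes and bad spacing", {
  a <- array(1, c(4, 4, 4))
  v <- vol3(a)
  expect_error(resampleVolume(v, c(1, 0, 1)), "positive")
  v@voxels[1] <- NA_real_
  expect_error(resampleVolume(v, c(1, 1, 1)), "non-finite")
})

test_that("subtraction is exact voxelwise post minus pre", {
  set.seed(2)
  pre <- vol3(array(rnorm(64), c(4, 4, 4)))
  expect_true(all(voxels(makeSubtraction(pre, pre)) == 0))
  post <- vol3(array(rnorm(64), c(4, 4, 4)))
  sub <- voxels(makeSubtraction(pre, post))
  # brute-force elementwise oracle
  oracle <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    oracle[i, j, k] <- voxels(post)[i, j, k] - voxels(pre)[i, j, k]
  expect_identical(sub, oracle)
  flipped <- makeSubtraction(pre, post, direction = "pre_minus_post")
  expect_identical(voxels(flipped), -sub)
})

test_that("subtraction of a noiseless contrast pair recovers the enhancement", {
  spec <- microSpec(noiseSD = 0, lesionIntensityDelta = 100, lesionPrevalence = 1)
  pair <- generateContrastPair(spec, seed = 5)
  sub <- voxels(makeSubtraction(pair$pre, pair$post))
  expect_true(all(sub[pair$truthMask == 1] == 100))
  expect_true(all(sub[pair$truthMask == 0] == 0))
})

test_that("subtraction rejects incongruent shapes naming both", {
  a <- vol3(array(0, c(2, 4, 4)))
  b <- vol3(array(0, c(2, 4, 5)))
  expect_error(makeSubtraction(a, b), "2x4x4.*2x4x5")
})

test_that("foreground crop of a uniform volume is the central window", {
  v <- vol3(array(1, c(2, 10, 12)))
  out <- foregroundCenterCrop(v, 4, 6)
  expect_identical(dim(voxels(out)), c(2L, 4L, 6L))
  expect_true(all(voxels(out) == 1))
  # matches an explicit center crop
  expect_identical(voxels(out), voxels(spatialCrop(v, c(2, 4, 6), "center")))
})

test_that("foreground crop centres on a single bright voxel", {
  a <- array(0, c(3, 20, 20))
  a[2, 5, 13] <- 10
  out <- foregroundCenterCrop(vol3(a), 6, 6)
  # window rows 2..7, cols 10..15, hand-computed from centroid (5, 13)
  expect_identical(voxels(out), a[, 2:7, 10:15, drop = FALSE])
  expect_identical(voxels(out)[2, 4, 4], 10)
})

test_that("full-frame foreground crop is the identity", {
  set.seed(3)
  a <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  expect_identical(voxels(foregroundCenterCrop(vol3(a), 8, 8)), a)
})

test_that("spatial crops: identity, centered offsets, seeded determinism", {
  set.seed(4)
  a <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  v <- vol3(a)
  expect_identical(voxels(spatialCrop(v, c(6, 6, 6), "center")), a)
  expect_identical(voxels(spatialCrop(v, c(6, 6, 6), "random", seed = 1)), a)
  cc <- spatialCrop(v, c(4, 4, 4), "center")
  expect_identical(voxels(cc), a[2:5, 2:5, 2:5])   # offset floor((6-4)/2) = 1
  r1 <- spatialCrop(v, c(3, 4, 2), "random", seed = 7)
  r2 <- spatialCrop(v, c(3, 4, 2), "random", seed = 7)
  expect_identical(voxels(r1), voxels(r2))
})

test_that("random crops stay within bounds and preserve intensities", {
  set.seed(5)
  a <- array(rnorm(5 * 7 * 9), c(5, 7, 9))
  v <- vol3(a)
  for (s in 1:10) {
    out <- voxels(spatialCrop(v, c(3, 3, 3), "random", seed = s))
    expect_true(all(out %in% a))
  }
})

test_that("mask-centred crop matches the center crop for a central voxel", {
  set.seed(6)
  a <- array(rnorm(7 * 7 * 7), c(7, 7, 7))
  mask <- array(0, c(7, 7, 7))
  mask[4, 4, 4] <- 1
  out <- cropAroundMask(vol3(a), mask, c(3, 3, 3))
  expect_identical(voxels(out), voxels(spatialCrop(vol3(a), c(3, 3, 3), "center")))
})

test_that("mask-centred crop clips at corners, keeping the mask inside", {
  set.seed(7)
  a <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  mask <- array(0, c(8, 8, 8))
  mask[1, 1:2, 1] <- 1
  out <- cropAroundMask(vol3(a), mask, c(4, 4, 4))
  # hand-computed: bbox centre (1, 1.5, 1) -> starts clipped to (1, 1, 1)
  expect_identical(voxels(out), a[1:4, 1:4, 1:4])
})

test_that("mask-centred crop pads symmetrically when the window is larger", {
  a <- array(1:27 * 1.0, c(3, 3, 3))
  mask <- array(0, c(3, 3, 3))
  mask[2, 2, 2] <- 1
  out <- voxels(cropAroundMask(vol3(a), mask, c(5, 5, 5)))
  expect_identical(dim(out), c(5L, 5L, 5L))
  expect_identical(out[2:4, 2:4, 2:4], a)          # mask centre stays central
  expect_true(all(out[1, , ] == min(a)))           # padding value
})

test_that("consensus follows the at-least-two-of-four rule on the 2x2 toy", {
  # per-voxel reader counts (2, 1, 4, 0)
  m <- function(v) array(v, c(1, 2, 2))
  masks <- list(m(c(1, 1, 1, 0)), m(c(1, 0, 1, 0)),
                m(c(0, 0, 1, 0)), m(c(0, 0, 1, 0)))
  expect_identical(as.vector(consensusMask(masks, 2)), c(1, 0, 1, 0))
  empty <- lapply(1:4, function(i) m(rep(0, 4)))
  expect_true(all(consensusMask(empty) == 0))
})

test_that("consensus equals the brute-force counting oracle on random sets", {
  set.seed(8)
  for (rep in 1:50) {
    masks <- lapply(1:4, function(i)
      array(rbinom(2 * 3 * 3, 1, 0.4), c(2, 3, 3)))
    k <- sample(1:4, 1)
    got <- consensusMask(masks, k)
    oracle <- array(0, c(2, 3, 3))
    for (i in 1:2) for (j in 1:3) for (l in 1:3) {
      cnt <- sum(vapply(masks, function(m) m[i, j, l], numeric(1)))
      oracle[i, j, l] <- as.numeric(cnt >= k)
    }
    expect_identical(got, oracle)
  }
})

test_that("consensus is monotone in the reader threshold, union to intersection", {
  set.seed(9)
  masks <- lapply(1:4, function(i) array(rbinom(36, 1, 0.5), c(4, 3, 3)))
  prev <- consensusMask(masks, 1)
  expect_identical(prev, (Reduce(`+`, masks) >= 1) * 1)   # union
  for (k in 2:4) {
    cur <- consensusMask(masks, k)
    expect_true(all(cur <= prev))                          # never adds voxels
    prev <- cur
  }
  expect_identical(prev, (Reduce(`+`, masks) == 4) * 1)    # intersection
})

test_that("consensus rejects incongruent reader masks", {
  masks <- list(array(0, c(2, 2, 2)), array(0, c(2, 2, 3)))
  expect_error(consensusMask(masks, 1), "incongruent")
})

test_that("nodule labelling follows the rating and size rules", {
  m <- array(1, c(2, 2, 2))
  ann <- function(r, d) AnnotationSet(rep(list(m), length(r)), r, d)
  expect_identical(deriveNoduleLabel(ann(c(4, 4, 5, 5), 10))@verdict, "malignant")
  d3 <- deriveNoduleLabel(ann(c(3, 3, 3, 3), 10))
  expect_identical(d3@verdict, "excluded")
  expect_identical(d3@reason, "ambiguous_rating")
  expect_identical(deriveNoduleLabel(ann(c(1, 2, 2, 1), 10))@verdict, "benign")
  small <- deriveNoduleLabel(ann(c(5, 5, 5, 5), 2.9))
  expect_identical(small@verdict, "excluded")
  expect_identical(small@reason, "small_nodule")
})

test_that("labelling matches a threshold oracle on randomized annotation sets", {
  set.seed(10)
  m <- array(1, c(2, 2, 2))
  for (rep in 1:100) {
    r <- sample(1:5, sample(1:4, 1), replace = TRUE)
    d <- runif(1, 0, 12)
    got <- deriveNoduleLabel(AnnotationSet(rep(list(m), length(r)), r, d))
    want <- if (d < 3) c("excluded", "small_nodule")
            else if (mean(r) > 3) c("malignant", "ok")
            else if (mean(r) < 3) c("benign", "ok")
            else c("excluded", "ambiguous_rating")
    expect_identical(c(got@verdict, got@reason), want)
  }
})

test_that("out-of-range ratings are rejected at construction or labelling", {
  m <- array(1, c(2, 2, 2))
  expect_error(AnnotationSet(list(m), 6, 10))
  expect_error(deriveNoduleLabel(AnnotationSet(list(m), 3, 10),
                                 minDiameterMM = -1), NA)
})
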
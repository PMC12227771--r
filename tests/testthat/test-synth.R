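test_that("zero prevalence always yields background-only negatives", {
  spec <- microSpec(lesionPrevalence = 0)
  for (s in 1:5) {
    case <- generateCase(spec, seed = s)
    expect_identical(case@label, 0L)
    expect_length(case@lesionSlices, 0)
    expect_true(all(case@lesionMask == 0))
  }
})

test_that("noiseless positives are the exact background + delta construction", {
  spec <- microSpec(noiseSD = 0, lesionIntensityDelta = 100,
                    lesionPrevalence = 1, background = 7)
  case <- generateCase(spec, seed = 3)
  v <- voxels(case@volume)
  expect_identical(case@label, 1L)
  expect_true(all(v[case@lesionMask == 0] == 7))
  expect_true(all(v[case@lesionMask == 1] == 107))
  expect_gt(sum(case@lesionMask), 0)
})

test_that("generation is bit-reproducible in the seed and sensitive to it", {
  spec <- microSpec()
  a <- generateCase(spec, seed = 42)
  b <- generateCase(spec, seed = 42)
  c <- generateCase(spec, seed = 43)
  expect_identical(voxels(a@volume), voxels(b@volume))
  expect_identical(a@lesionMask, b@lesionMask)
  expect_false(identical(voxels(a@volume), voxels(c@volume)))
})

test_that("lesion slices are contiguous and consistent with the mask", {
  spec <- microSpec(lesionPrevalence = 1)
  for (s in 1:10) {
    case <- generateCase(spec, seed = s)
    expect_true(all(diff(case@lesionSlices) == 1L))
    onMask <- which(apply(case@lesionMask, 1, sum) > 0)
    expect_identical(onMask, as.integer(case@lesionSlices))
  }
})

test_that("positive fraction matches the prevalence within the binomial bound", {
  spec <- synthSpec(nSlices = 4, height = 8, width = 8, noiseSD = 0,
                    lesionRadiusRange = c(1, 2), lesionSlabRange = c(2, 3),
                    lesionPrevalence = 0.3)
  labels <- vapply(generateDataset(spec, 1000, seed = 5),
                   function(case) case@label, integer(1))
  p <- spec$lesionPrevalence
  expect_lt(abs(mean(labels) - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("noiseless contrast pair subtracts to exactly delta on the mask", {
  spec <- microSpec(noiseSD = 0, lesionIntensityDelta = 100, lesionPrevalence = 1)
  pair <- generateContrastPair(spec, seed = 2)
  d <- voxels(pair$post) - voxels(pair$pre)
  expect_true(all(d[pair$truthMask == 1] == 100))
  expect_true(all(d[pair$truthMask == 0] == 0))
})

test_that("null enhancement leaves a near-zero-mean noise subtraction", {
  spec <- microSpec(lesionIntensityDelta = 0, lesionPrevalence = 1, noiseSD = 0.5)
  pair <- generateContrastPair(spec, seed = 9)
  d <- voxels(pair$post) - voxels(pair$pre)
  expect_lt(abs(mean(d)), 5 * 0.5 * sqrt(2) / sqrt(length(d)))
})

test_that("contrast pairs regenerate identically under the same seed", {
  spec <- microSpec()
  p1 <- generateContrastPair(spec, seed = 4)
  p2 <- generateContrastPair(spec, seed = 4)
  expect_identical(voxels(p1$pre), voxels(p2$pre))
  expect_identical(voxels(p1$post), voxels(p2$post))
  expect_identical(p1$truthMask, p2$truthMask)
})

test_that("zero disagreement reproduces the true mask for every reader", {
  mask <- generateCase(microSpec(lesionPrevalence = 1), 3)@lesionMask
  ann <- generateMultireader(mask, ratingsCenter = 5, disagreement = 0,
                             ratingJitter = 0, seed = 1)
  for (m in ann@readerMasks) expect_identical(m, mask)
  expect_identical(ann@ratings, rep(5, 4))
})

test_that("full disagreement toggles exactly the boundary voxels", {
  mask <- array(0, c(4, 6, 6))
  mask[2:3, 3:4, 3:4] <- 1
  nBoundary <- length(sliceformer:::maskBoundary(mask))
  ann <- generateMultireader(mask, ratingsCenter = 3, disagreement = 1, seed = 8)
  for (m in ann@readerMasks)
    expect_identical(sum(m != mask), nBoundary)
})

test_that("multireader rejects invalid reader counts and ratings centers", {
  mask <- array(c(0, 1), c(2, 2, 2))
  expect_error(generateMultireader(mask, 3, 0.1, nReaders = 0), "nReaders")
  expect_error(generateMultireader(mask, 9, 0.1), "ratingsCenter")
})

test_that("invalid generator specs are rejected with informative messages", {
  expect_error(synthSpec(nSlices = 3), "nSlices")
  expect_error(synthSpec(noiseSD = -1), "noiseSD")
  expect_error(synthSpec(lesionSlabRange = c(2, 50)), "lesionSlabRange")
  expect_error(synthSpec(lesionPrevalence = 1.2), "lesionPrevalence")
})

test_that("cases round-trip through NIfTI files with metadata", {
  dir <- withr::local_tempdir()
  cases <- generateDataset(microSpec(), 3, seed = 6)
  meta <- writeCases(cases, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_identical(meta$label,
                   vapply(cases, function(case) case@label, integer(1)))
  v <- readVolume(meta$volume_path[1])
  expect_equal(voxels(v), voxels(cases[[1]]@volume), tolerance = 1e-6)
  expect_equal(spacing(v), spacing(cases[[1]]@volume), tolerance = 1e-6)
})
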
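test_that("early stopping keeps the best epoch and stops after patience", {
  r <- earlyStoppingReplay(c(0.6, 0.7, 0.65, 0.66), patience = 2)
  expect_identical(r$bestEpoch, 2L)
  expect_identical(r$stoppedEpoch, 4L)
  r2 <- earlyStoppingReplay(seq(0.5, 0.9, by = 0.1), patience = 2)
  expect_identical(r2$bestEpoch, 5L)       # strictly increasing: runs out
  expect_identical(r2$stoppedEpoch, 5L)
  r3 <- earlyStoppingReplay(c(0.7, 0.7, 0.7), patience = 2)
  expect_identical(r3$bestEpoch, 1L)       # ties are not improvements
  expect_identical(r3$stoppedEpoch, 3L)
})

test_that("signal inversion and flips are involutions", {
  set.seed(1)
  v <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  inv2 <- augmentVolume(augmentVolume(v, "signal_inversion", forceApply = TRUE),
                        "signal_inversion", forceApply = TRUE)
  expect_equal(inv2, v, tolerance = 1e-12)
  f1 <- augmentVolume(v, "flip", seed = 5, forceApply = TRUE)
  f2 <- augmentVolume(f1, "flip", seed = 5, forceApply = TRUE)  # same axis
  expect_identical(f2, v)
})

test_that("augmentation is reproducible under a fixed seed", {
  set.seed(2)
  v <- array(rnorm(4 * 12 * 12), c(4, 12, 12))
  all4 <- c("flip", "gaussian_noise", "rotation", "signal_inversion")
  a1 <- augmentVolume(v, all4, seed = 9)
  a2 <- augmentVolume(v, all4, seed = 9)
  expect_identical(a1, a2)
  a3 <- augmentVolume(v, all4, seed = 10)
  expect_false(identical(a1, a3))
})

test_that("rotation interpolates linearly and respects the angle range", {
  v <- array(rnorm(2 * 16 * 16), c(2, 16, 16))
  r <- augmentVolume(v, "rotation", seed = 3, forceApply = TRUE)
  expect_identical(dim(r), dim(v))
  expect_true(all(is.finite(r)))
  # rotating by ~0 degrees is near-identity
  r0 <- augmentVolume(v, "rotation", seed = 3, rotationRange = 1e-9,
                      forceApply = TRUE)
  expect_equal(r0, v, tolerance = 1e-6)
})

test_that("class-balanced weights invert the class frequencies", {
  w <- classBalancedWeights(c(0, 0, 0, 1))
  expect_equal(w[4] / w[1], 3, tolerance = 1e-12)
  expect_equal(classBalancedWeights(c(0, 1, 0, 1)), rep(0.5, 4))
  expect_error(classBalancedWeights(c(1, 1, 1)), "both classes")
})

test_that("weighted draws hit a balanced class ratio", {
  labels <- c(0, 0, 0, 1)
  w <- classBalancedWeights(labels)
  set.seed(4)
  draws <- sample(labels, 10000, replace = TRUE, prob = w)
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.5 / sqrt(10000))
})

microFit <- function(frozen = FALSE, seed = 21, epochs = 4) {
  enc <- microVitConfig(frozen = frozen)
  agg <- microAggConfig("transformer", nSlices = 6)
  model <- buildMST(enc, agg, seed = seed)
  ds <- microDataset(28, seed = seed)
  split <- stratifiedGroupSplit(ds$labels, fractions = c(0.75, 0.25),
                                valFraction = 0.3, seed = seed)
  tr <- sliceformer:::subsetDataset(ds, split@trainIds)
  va <- sliceformer:::subsetDataset(ds, split@valIds)
  cfg <- trainConfig(lr = 1e-3, maxEpochs = epochs, patience = 50, seed = seed)
  list(fit = trainModel(model, tr, va, cfg), tr = tr, va = va, model = model)
}

test_that("the best checkpoint reproduces its recorded validation AUC exactly", {
  r <- microFit()
  fit <- r$fit
  expect_s4_class(fit$history, "TrainHistory")
  expect_identical(max(fit$history@epochs$valAUC), fit$bestValAUC)
  expect_identical(fit$history@epochs$valAUC[fit$history@bestEpoch],
                   fit$bestValAUC)
  # re-evaluating the returned (best) model gives the recorded value exactly
  scores <- sliceformer:::scoreVolumes(fit$model, r$va$volumes)
  expect_identical(aucScore(scores, r$va$labels), fit$bestValAUC)
})

test_that("training is bit-reproducible under a fixed seed", {
  r1 <- microFit(seed = 22, epochs = 2)
  r2 <- microFit(seed = 22, epochs = 2)
  expect_identical(r1$fit$history@epochs, r2$fit$history@epochs)
  expect_identical(r1$fit$model@aggregator@params, r2$fit$model@aggregator@params)
  expect_identical(r1$fit$model@encoder@params, r2$fit$model@encoder@params)
})

test_that("a frozen encoder is bit-identical after training, the head is not", {
  r <- microFit(frozen = TRUE, epochs = 2)
  before <- buildMST(microVitConfig(frozen = TRUE),
                     microAggConfig("transformer", nSlices = 6), seed = 21)
  expect_identical(r$fit$model@encoder@params, before@encoder@params)
  expect_false(identical(r$fit$model@aggregator@params,
                         before@aggregator@params))
})

test_that("unfrozen encoders do change during training", {
  r <- microFit(frozen = FALSE, epochs = 2, seed = 23)
  before <- buildMST(microVitConfig(), microAggConfig("transformer",
                                                      nSlices = 6), seed = 23)
  expect_false(identical(r$fit$model@encoder@params, before@encoder@params))
})

test_that("single-class sets and bad configs are rejected", {
  ds <- microDataset(8, seed = 30)
  onlyPos <- sliceformer:::subsetDataset(ds, which(ds$labels == ds$labels[1]))
  model <- buildMST(microVitConfig(), microAggConfig(nSlices = 6), seed = 1)
  expect_error(trainModel(model, onlyPos, ds), "both classes")
  expect_error(trainConfig(lr = -1), "positive")
  expect_error(trainConfig(patience = 0), "patience")
  expect_error(trainConfig(augmentations = "zoom"), "unknown aug")
})
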
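test_that("AUC equals the Mann-Whitney concordance", {
  expect_identical(aucScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_identical(aucScore(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  expect_identical(aucScore(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
})

test_that("AUC matches pairwise counting and is monotone-invariant", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
    expect_equal(aucScore(scores, labels), aucByCounting(scores, labels),
                 tolerance = 1e-12)
    expect_equal(aucScore(exp(3 * scores), labels), aucScore(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(2)
  labels <- rbinom(60, 1, 0.4)
  labels[1:2] <- c(0, 1)
  scores <- rnorm(60)
  expect_equal(aucScore(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   levels = c(0, 1), direction = "<"))),
               tolerance = 1e-12)
})

test_that("single-class inputs are rejected", {
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("identical paired scores give the degenerate p = 1 convention", {
  s <- rnorm(20)
  labels <- rep(c(0, 1), 10)
  r <- deLongTest(s, s, labels)
  expect_identical(r$p, 1)
  expect_true(r$degenerate)
  expect_identical(r$aucA, r$aucB)
})

test_that("fast DeLong matches the quadratic structural-component oracle", {
  set.seed(3)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    labels <- c(0, 0, 1, 1, rbinom(n - 4, 1, runif(1, 0.25, 0.75)))
    a <- rnorm(n) + labels * runif(1, 0, 2)
    b <- rnorm(n) + labels * runif(1, 0, 2)
    if (rep %% 3 == 0) { a <- round(a, 1); b <- round(b, 1) }  # ties
    fast <- deLongTest(a, b, labels)
    slow <- delongOracle(a, b, labels)
    expect_lt(abs(fast$p - slow$p), 1e-10)
    expect_lt(abs(fast$z - slow$z), 1e-8)
    expect_equal(fast$aucA, slow$aucA, tolerance = 1e-12)
  }
})

test_that("DeLong agrees with an established implementation", {
  set.seed(4)
  labels <- c(0, 1, rbinom(58, 1, 0.5))
  a <- rnorm(60) + labels
  b <- rnorm(60) + 0.5 * labels
  fast <- deLongTest(a, b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE,
                                  levels = c(0, 1), direction = "<"),
                        pROC::roc(labels, b, quiet = TRUE,
                                  levels = c(0, 1), direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(fast$p, ref$p.value, tolerance = 1e-9)
})

test_that("bootstrap interval collapses for perfect separation and is seeded", {
  labels <- rep(c(0, 1), each = 25)
  scores <- c(rnorm(25, 0), rnorm(25, 10))
  b <- bootstrapCI(scores, labels, nBoot = 200, seed = 5)
  expect_identical(c(b$lo, b$hi), c(1, 1))
  expect_identical(b$sd, 0)
  b2 <- bootstrapCI(scores, labels, nBoot = 200, seed = 5)
  expect_identical(b$aucs, b2$aucs)
})

test_that("bootstrap intervals contain the point AUC on random data", {
  set.seed(6)
  for (rep in 1:25) {
    labels <- c(0, 1, rbinom(38, 1, 0.5))
    scores <- rnorm(40) + 0.5 * labels
    b <- bootstrapCI(scores, labels, nBoot = 300, seed = rep)
    a <- aucScore(scores, labels)
    expect_true(b$lo <= a && a <= b$hi)
  }
})

test_that("a balanced 10-sample split lands at 8 train-val (4/4) and 2 test (1/1)", {
  labels <- rep(c(0L, 1L), 5)
  s <- stratifiedGroupSplit(labels, seed = 7)
  expect_identical(length(s@testIds), 2L)
  expect_identical(sort(labels[s@testIds]), c(0L, 1L))
  tv <- c(s@trainIds, s@valIds)
  expect_identical(length(tv), 8L)
  expect_identical(sum(labels[tv]), 4L)
  expect_setequal(c(tv, s@testIds), 1:10)
})

test_that("splits are reproducible and partitions disjoint", {
  set.seed(8)
  labels <- rbinom(60, 1, 0.4)
  labels[1:4] <- c(0, 0, 1, 1)
  s1 <- stratifiedGroupSplit(labels, seed = 9)
  s2 <- stratifiedGroupSplit(labels, seed = 9)
  expect_identical(s1@trainIds, s2@trainIds)
  expect_identical(s1@testIds, s2@testIds)
  expect_length(intersect(s1@trainIds, s1@testIds), 0)
  expect_length(intersect(s1@valIds, s1@testIds), 0)
  expect_setequal(c(s1@trainIds, s1@valIds, s1@testIds), seq_along(labels))
})

test_that("groups are never split across partitions", {
  # six groups of two samples, one positive + one negative each
  labels <- rep(c(0, 1), 6)
  groups <- rep(1:6, each = 2)
  for (seed in 1:10) {
    s <- stratifiedGroupSplit(labels, groups, seed = seed)
    for (part in list(s@trainIds, s@valIds, s@testIds)) {
      gs <- groups[part]
      expect_true(all(table(gs) == 2))   # both members co-located
    }
  }
})

test_that("an unplaceable group is rejected by name", {
  labels <- c(rep(1, 10), rep(0, 4))
  groups <- c(rep("bigpos", 10), letters[1:4])
  expect_error(stratifiedGroupSplit(labels, groups, seed = 1), "bigpos")
})

test_that("localization proxies follow the argmax conventions", {
  vals <- array(0, c(4, 5, 5))
  mask <- array(0, c(4, 5, 5))
  mask[3, 3, 3] <- 1
  vals[3, 3, 3] <- 1                      # all mass on the lesion voxel
  pr <- localizationProxies(vals, 3L, mask)
  expect_true(pr$sliceHit && pr$lesionHit)
  uniform <- array(1, c(4, 5, 5)) / 100   # ties: argmax falls to index 1
  pr2 <- localizationProxies(uniform, 3L, mask)
  expect_false(pr2$sliceHit)
  expect_false(pr2$lesionHit)
  expect_error(localizationProxies(vals, integer(0), mask), "empty ground truth")
})

test_that("proxies agree with construction on a randomized battery", {
  set.seed(10)
  for (rep in 1:100) {
    d <- c(6, 7, 7)
    mask <- array(0, d)
    centre <- c(sample(2:5, 1), sample(2:6, 1), sample(2:6, 1))
    mask[centre[1], centre[2], centre[3]] <- 1
    vals <- array(runif(prod(d), 0, 0.5), d)
    peakInside <- runif(1) < 0.5
    peak <- if (peakInside) centre + sample(-1:1, 3, replace = TRUE)
            else c(1, 1, 1)
    vals[peak[1], peak[2], peak[3]] <- 10          # unique global max
    pr <- localizationProxies(vals, centre[1], mask)
    expect_identical(pr$lesionHit, peakInside || all(abs(peak - centre) <= 1))
    expect_identical(pr$sliceHit,
                     which.max(apply(vals, 1, sum)) == centre[1])
  }
})

test_that("model evaluation assembles AUC, confusion and comparison", {
  ds <- microDataset(16, seed = 11)
  model <- buildMST(microVitConfig(), microAggConfig(nSlices = 6), seed = 11)
  set.seed(12)
  ref <- runif(16)
  r <- evaluateModel(model, ds, refScores = ref, nBoot = 100, seed = 12)
  expect_s4_class(r, "EvalResult")
  expect_true(r@auc >= 0 && r@auc <= 1)
  expect_true(r@ci95[1] <= r@auc && r@auc <= r@ci95[2])
  expect_identical(sum(r@confusion), length(ds$labels))
  expect_true(r@delongP > 0 && r@delongP <= 1)
})
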
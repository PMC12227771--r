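test_that("classification-token attention extraction normalizes and averages", {
  expect_equal(extractClsAttention(matrix(c(2, 3, 5), 1)), c(0.2, 0.3, 0.5),
               tolerance = 1e-12)
  two <- rbind(rep(1, 8), rep(3, 8))         # two uniform heads over k tokens
  expect_equal(extractClsAttention(two), rep(1 / 8, 8), tolerance = 1e-12)
})

test_that("attention extraction matches the per-head loop oracle", {
  set.seed(1)
  for (rep in 1:20) {
    h <- sample(2:6, 1)
    tok <- sample(5:12, 1)
    A <- matrix(runif(h * tok), h)
    drop <- seq_len(sample(1:2, 1))
    got <- extractClsAttention(A, dropCols = drop)
    kept <- A[, -drop, drop = FALSE]
    oracle <- rep(0, ncol(kept))
    for (i in seq_len(h)) oracle <- oracle + kept[i, ] / sum(kept[i, ])
    oracle <- oracle / h
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("degenerate all-zero attention rows are rejected", {
  A <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_error(extractClsAttention(A, dropCols = 1L), "degenerate")
})

test_that("fusion concentrates mass exactly where slice weights put it", {
  maps <- list(matrix(1 / 4, 2, 2), matrix(c(1, 0, 0, 0), 2, 2))
  b <- combineAttention(c(1, 0), maps, c(8, 8))
  expect_equal(sum(b@combined[1, , ]), 1, tolerance = 1e-6)
  expect_true(all(b@combined[2, , ] == 0))
  u <- combineAttention(c(0.5, 0.5), list(matrix(1 / 4, 2, 2), matrix(1 / 4, 2, 2)),
                        c(6, 6))
  expect_equal(sum(u@combined), 1, tolerance = 1e-6)
  expect_true(max(u@combined) - min(u@combined) < 1e-12)  # uniform in, uniform out
})

test_that("fused per-slice mass equals the slice weights on random inputs", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    w <- runif(n); w <- w / sum(w)
    maps <- lapply(seq_len(n), function(i) {
      m <- matrix(runif(16), 4); m / sum(m)
    })
    b <- combineAttention(w, maps, c(12, 10))
    expect_lt(max(abs(apply(b@combined, 1, sum) - w)), 1e-5)
    expect_lt(abs(sum(b@combined) - 1), 1e-5)
    expect_true(all(b@combined >= 0))
  }
})

test_that("fusion commutes with slice permutations", {
  set.seed(3)
  n <- 5
  w <- runif(n); w <- w / sum(w)
  maps <- lapply(1:n, function(i) { m <- matrix(runif(9), 3); m / sum(m) })
  perm <- sample(n)
  a <- combineAttention(w, maps, c(7, 7))
  b <- combineAttention(w[perm], maps[perm], c(7, 7))
  expect_equal(a@combined[perm, , ], b@combined, tolerance = 1e-12)
})

test_that("fusion rejects mismatched or unnormalized inputs", {
  m <- matrix(1 / 4, 2, 2)
  expect_error(combineAttention(c(1, 0), list(m), c(4, 4)), "mismatch")
  expect_error(combineAttention(c(0.7, 0.7), list(m, m), c(4, 4)), "sum to 1")
  expect_error(combineAttention(c(0.5, 0.5), list(m, 2 * m), c(4, 4)), "map 2")
})

test_that("activation-gradient maps follow the clip-and-sum definition", {
  expect_true(all(gradCAM3D(array(rnorm(24), c(2, 3, 4)),
                            array(0, c(2, 3, 4)))@values == 0))
  ind <- array(0, c(3, 3, 3)); ind[2, 1, 3] <- 1
  expect_identical(gradCAM3D(ind, ind)@values, ind)  # indicator is preserved
})

test_that("activation-gradient maps match an explicit loop oracle", {
  set.seed(4)
  for (rep in 1:10) {
    d <- c(2, 3, 3, 4)
    a <- array(rnorm(prod(d)), d)
    g <- array(rnorm(prod(d)), d)
    got <- gradCAM3D(a, g)@values
    oracle <- array(0, d[1:3])
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      oracle[i, j, k] <- max(0, sum(a[i, j, k, ] * g[i, j, k, ]))
    expect_equal(got, oracle, tolerance = 1e-6)
    # channel-pooled variant against its own oracle
    gotP <- gradCAM3D(a, g, pooled = TRUE)@values
    w <- apply(g, 4, mean)
    oracleP <- array(0, d[1:3])
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      oracleP[i, j, k] <- max(0, sum(a[i, j, k, ] * w))
    expect_equal(gotP, oracleP, tolerance = 1e-6)
  }
})

test_that("resized activation-gradient maps stay nonnegative and congruent", {
  set.seed(5)
  a <- array(abs(rnorm(36)), c(2, 3, 3, 2))
  g <- array(rnorm(36), c(2, 3, 3, 2))
  sal <- gradCAM3D(a, g, outShape = c(4, 9, 9))
  expect_identical(dim(sal@values), c(4L, 9L, 9L))
  expect_true(all(sal@values >= 0))
  expect_error(gradCAM3D(a, g[, , , 1, drop = FALSE]), "mismatch")
})

test_that("model-level attention saliency is a valid bundle on a volume", {
  model <- buildMST(microVitConfig(), microAggConfig(nSlices = 4), seed = 6)
  vol <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  sal <- computeSaliency(model, vol)
  expect_identical(sal@method, "attention_fusion")
  expect_identical(dim(sal@values), dim(vol))
  expect_equal(sum(sal@values), 1, tolerance = 1e-5)
  b <- attr(sal, "bundle")
  expect_s4_class(b, "AttentionBundle")
  expect_equal(apply(sal@values, 1, sum), b@sliceWeights, tolerance = 1e-5)
})

test_that("saliency volumes export as NIfTI", {
  dir <- withr::local_tempdir()
  sal <- gradCAM3D(array(abs(rnorm(27)), c(3, 3, 3)),
                   array(rnorm(27), c(3, 3, 3)))
  p <- writeSaliency(sal, file.path(dir, "sal.nii.gz"), spacing = c(3, 1, 1))
  v <- readVolume(p)
  expect_equal(voxels(v), sal@values, tolerance = 1e-6)
})
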
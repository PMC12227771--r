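# Residual networks: the canonical layout with every k x k kernel inflated to
# k x k x k for the 3D reference classifier, and the 2D variant (depth-1
# kernels) used as an alternative slice encoder with its final linear layer
# removed.

#' 3D residual-network configuration
#'
#' Canonical residual layouts: basic blocks for depth 18/34, bottlenecks for
#' 50/101/152, channel widths 64-512 (x4 expansion for bottlenecks), a 7^3
#' stem convolution with stride 2, max pooling, four residual stages, global
#' average pooling and an affine head. Trainable parameter counts: 33.2M
#' (depth 18), 46.2M (50), 85.2M (101), 117.4M (152).
#'
#' @param depth one of 18, 34, 50, 101, 152.
#' @param nClasses number of output classes.
#' @param inChannels input channels (1 for grayscale volumes).
#' @return a list of class `"resnetConfig"`.
#' @export
resnetConfig <- function(depth = 50L, nClasses = 2L, inChannels = 1L) {
  resnetConfigDims(depth, nClasses, inChannels, dims = 3L)
}

#' 2D residual slice-encoder configuration
#'
#' The 2D residual network with the classification head removed; the
#' post-pooling feature vector (512 dimensions for the basic-block depths)
#' is used as the slice feature. Grayscale slices are replicated to three
#' channels, keeping the layout compatible with externally obtained
#' natural-image weights.
#'
#' @param depth one of 18, 34, 50.
#' @return a list of class `"cnnConfig"`.
#' @export
cnnConfig <- function(depth = 18L) {
  cfg <- resnetConfigDims(depth, nClasses = 0L, inChannels = 3L, dims = 2L)
  cfg$family <- "cnn2d"
  cfg$embedDim <- cfg$outChannels
  class(cfg) <- c("cnnConfig", "list")
  cfg
}

resnetConfigDims <- function(depth, nClasses, inChannels, dims) {
  depth <- as.integer(depth)
  spec <- switch(as.character(depth),
    "18" = list(layers = c(2L, 2L, 2L, 2L), bottleneck = FALSE),
    "34" = list(layers = c(3L, 4L, 6L, 3L), bottleneck = FALSE),
    "50" = list(layers = c(3L, 4L, 6L, 3L), bottleneck = TRUE),
    "101" = list(layers = c(3L, 4L, 23L, 3L), bottleneck = TRUE),
    "152" = list(layers = c(3L, 8L, 36L, 3L), bottleneck = TRUE),
    stop("unsupported depth ", depth, "; allowed: 18, 34, 50, 101, 152"))
  cfg <- list(depth = depth, layers = spec$layers, bottleneck = spec$bottleneck,
              nClasses = as.integer(nClasses), inChannels = as.integer(inChannels),
              dims = as.integer(dims), mids = c(64L, 128L, 256L, 512L))
  cfg$outChannels <- if (spec$bottleneck) 2048L else 512L
  class(cfg) <- c("resnetConfig", "list")
  cfg
}

rnKernel <- function(cfg, k) if (cfg$dims == 3L) rep(k, 3L) else c(1L, k, k)
rnStride <- function(cfg, s) if (cfg$dims == 3L) rep(s, 3L) else c(1L, s, s)
rnPad <- function(cfg, p) if (cfg$dims == 3L) rep(p, 3L) else c(0L, p, p)

resnetParamShapes <- function(cfg) {
  convS <- function(k, cin, cout) list(W = c(rnKernel(cfg, k), cin, cout))
  bnS <- function(c) list(g = c, b = c)
  blocks <- list()
  inC <- 64L
  for (s in 1:4) {
    mid <- cfg$mids[s]
    outC <- if (cfg$bottleneck) 4L * mid else mid
    stage <- list()
    for (b in seq_len(cfg$layers[s])) {
      blk <- if (cfg$bottleneck)
        list(conv1 = convS(1, inC, mid), bn1 = bnS(mid),
             conv2 = convS(3, mid, mid), bn2 = bnS(mid),
             conv3 = convS(1, mid, outC), bn3 = bnS(outC))
      else
        list(conv1 = convS(3, inC, mid), bn1 = bnS(mid),
             conv2 = convS(3, mid, mid), bn2 = bnS(outC))
      if (b == 1L && (s > 1L || inC != outC))
        blk$down <- list(conv = convS(1, inC, outC), bn = bnS(outC))
      stage[[b]] <- blk
      inC <- outC
    }
    blocks[[s]] <- stage
  }
  shapes <- list(stem = list(conv = convS(7, cfg$inChannels, 64L), bn = bnS(64L)),
                 stages = blocks)
  if (cfg$nClasses > 0L)
    shapes$fc <- list(W = c(cfg$outChannels, cfg$nClasses), b = cfg$nClasses)
  shapes
}

resnetInitParams <- function(cfg, seed) {
  shapes <- resnetParamShapes(cfg)
  withSeed(seed, {
    init <- function(s, name) {
      if (is.list(s)) {
        out <- lapply(seq_along(s), function(i) init(s[[i]], names(s)[i]))
        names(out) <- names(s)
        return(out)
      }
      n <- prod(s)
      if (identical(name, "W") && length(s) > 2L) {
        fanIn <- prod(s[-length(s)])
        v <- stats::rnorm(n, sd = sqrt(2 / fanIn))    # He initialization
      } else if (identical(name, "g")) v <- rep(1, n)
      else if (identical(name, "b")) v <- rep(0, n)
      else v <- stats::rnorm(n, sd = 0.01)
      if (length(s) > 1L) array(v, s) else v
    }
    init(shapes, "")
  })
}

resnetInitState <- function(cfg) {
  shapes <- resnetParamShapes(cfg)
  # bn shape leaves hold channel counts; build zero-mean unit-var stats
  mk2 <- function(s) {
    if (is.list(s)) {
      if (identical(sort(names(s)), c("b", "g")) && !is.list(s$g))
        return(list(mean = rep(0, s$g), var = rep(1, s$g)))
      out <- lapply(s, mk2)
      names(out) <- names(s)
      return(out)
    }
    NULL
  }
  mk2(shapes)
}

#' Construct the 3D residual reference model
#'
#' @param cfg a [resnetConfig()] (or a depth, for convenience).
#' @param seed seed for He-normal weight initialization.
#' @return a [ResNet3D-class].
#' @examples
#' paramsMillions(resnetConfig(50))  # 46
#' @export
buildResNet3D <- function(cfg = resnetConfig(50L), seed = 1L) {
  if (is.numeric(cfg)) cfg <- resnetConfig(cfg)
  stopifnot(inherits(cfg, "resnetConfig"), cfg$dims == 3L)
  ResNet3D(config = cfg, params = resnetInitParams(cfg, seed),
           state = resnetInitState(cfg))
}

buildCNNEncoder <- function(cfg = cnnConfig(18L), seed = 1L) {
  stopifnot(inherits(cfg, "cnnConfig"))
  CNNEncoder(config = cfg, params = resnetInitParams(cfg, seed),
             state = resnetInitState(cfg))
}

# --- forward / backward -------------------------------------------------------

resnetBlockFwd <- function(x, p, st, cfg, stride, training, needCache) {
  convPad1 <- rnPad(cfg, 1L)
  if (cfg$bottleneck) {
    c1 <- conv3dFwd(x, p$conv1$W, rnStride(cfg, 1L), rnPad(cfg, 0L), needCache)
    b1 <- bnFwd(c1$out, p$bn1$g, p$bn1$b, st$bn1, training)
    r1 <- reluFwd(b1$out)
    c2 <- conv3dFwd(r1$out, p$conv2$W, stride, convPad1, needCache)
    b2 <- bnFwd(c2$out, p$bn2$g, p$bn2$b, st$bn2, training)
    r2 <- reluFwd(b2$out)
    c3 <- conv3dFwd(r2$out, p$conv3$W, rnStride(cfg, 1L), rnPad(cfg, 0L), needCache)
    b3 <- bnFwd(c3$out, p$bn3$g, p$bn3$b, st$bn3, training)
    main <- b3$out
  } else {
    c1 <- conv3dFwd(x, p$conv1$W, stride, convPad1, needCache)
    b1 <- bnFwd(c1$out, p$bn1$g, p$bn1$b, st$bn1, training)
    r1 <- reluFwd(b1$out)
    c2 <- conv3dFwd(r1$out, p$conv2$W, rnStride(cfg, 1L), convPad1, needCache)
    b2 <- bnFwd(c2$out, p$bn2$g, p$bn2$b, st$bn2, training)
    main <- b2$out
  }
  if (!is.null(p$down)) {
    cd <- conv3dFwd(x, p$down$conv$W, stride, rnPad(cfg, 0L), needCache)
    bd <- bnFwd(cd$out, p$down$bn$g, p$down$bn$b, st$down$bn, training)
    idn <- bd$out
  } else idn <- x
  rOut <- reluFwd(main + idn)
  newState <- list(bn1 = b1$state, bn2 = b2$state)
  if (cfg$bottleneck) newState$bn3 <- b3$state
  if (!is.null(p$down)) newState$down <- list(bn = bd$state)
  cache <- NULL
  if (needCache) {
    cache <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                  c2 = c2$cache, b2 = b2$cache, rOut = rOut$cache,
                  hasDown = !is.null(p$down))
    if (cfg$bottleneck) {
      cache$r2 <- r2$cache; cache$c3 <- c3$cache; cache$b3 <- b3$cache
    }
    if (!is.null(p$down)) { cache$cd <- cd$cache; cache$bd <- bd$cache }
  }
  list(out = rOut$out, state = newState, cache = cache)
}

resnetBlockBwd <- function(dy, cache, p, cfg) {
  dMain <- reluBwd(dy, cache$rOut)
  dIdn <- dMain
  if (cfg$bottleneck) {
    b3 <- bnBwd(dMain, cache$b3, p$bn3$g)
    c3 <- conv3dBwd(b3$dx, cache$c3, p$conv3$W)
    dr2 <- reluBwd(c3$dx, cache$r2)
    b2 <- bnBwd(dr2, cache$b2, p$bn2$g)
    c2 <- conv3dBwd(b2$dx, cache$c2, p$conv2$W)
    dr1 <- reluBwd(c2$dx, cache$r1)
    b1 <- bnBwd(dr1, cache$b1, p$bn1$g)
    c1 <- conv3dBwd(b1$dx, cache$c1, p$conv1$W)
    dx <- c1$dx
    grads <- list(conv1 = list(W = c1$dW), bn1 = list(g = b1$dg, b = b1$db),
                  conv2 = list(W = c2$dW), bn2 = list(g = b2$dg, b = b2$db),
                  conv3 = list(W = c3$dW), bn3 = list(g = b3$dg, b = b3$db))
  } else {
    b2 <- bnBwd(dMain, cache$b2, p$bn2$g)
    c2 <- conv3dBwd(b2$dx, cache$c2, p$conv2$W)
    dr1 <- reluBwd(c2$dx, cache$r1)
    b1 <- bnBwd(dr1, cache$b1, p$bn1$g)
    c1 <- conv3dBwd(b1$dx, cache$c1, p$conv1$W)
    dx <- c1$dx
    grads <- list(conv1 = list(W = c1$dW), bn1 = list(g = b1$dg, b = b1$db),
                  conv2 = list(W = c2$dW), bn2 = list(g = b2$dg, b = b2$db))
  }
  if (cache$hasDown) {
    bd <- bnBwd(dIdn, cache$bd, p$down$bn$g)
    cd <- conv3dBwd(bd$dx, cache$cd, p$down$conv$W)
    dx <- dx + cd$dx
    grads$down <- list(conv = list(W = cd$dW), bn = list(g = bd$dg, b = bd$db))
  } else {
    dx <- dx + dIdn
  }
  list(dx = dx, grads = grads[names(p)])
}

resnetForward <- function(params, state, cfg, x, training = FALSE,
                          needCache = FALSE) {
  cs <- conv3dFwd(x, params$stem$conv$W, rnStride(cfg, 2L), rnPad(cfg, 3L),
                  needCache)
  bs <- bnFwd(cs$out, params$stem$bn$g, params$stem$bn$b, state$stem$bn, training)
  rs <- reluFwd(bs$out)
  mp <- maxPool3dFwd(rs$out, rnKernel(cfg, 3L), rnStride(cfg, 2L),
                     rnPad(cfg, 1L), needCache)
  h <- mp$out
  newState <- list(stem = list(bn = bs$state), stages = state$stages)
  caches <- if (needCache) list(stem = list(c = cs$cache, b = bs$cache,
                                            r = rs$cache, mp = mp$cache),
                                stages = vector("list", 4)) else NULL
  for (s in 1:4) {
    nb <- length(params$stages[[s]])
    if (needCache) caches$stages[[s]] <- vector("list", nb)
    for (b in seq_len(nb)) {
      stride <- rnStride(cfg, if (s > 1L && b == 1L) 2L else 1L)
      bf <- resnetBlockFwd(h, params$stages[[s]][[b]], state$stages[[s]][[b]],
                           cfg, stride, training, needCache)
      h <- bf$out
      newState$stages[[s]][[b]] <- bf$state
      if (needCache) caches$stages[[s]][[b]] <- bf$cache
    }
  }
  gp <- globalAvgPoolFwd(h)
  out <- list(feature = gp$out, lastAct = h, state = newState)
  if (!is.null(params$fc)) {
    lf <- nnLinearFwd(matrix(gp$out, 1), params$fc)
    out$logits <- lf$out[1, ]
  }
  if (needCache) {
    caches$gap <- gp$cache
    caches$feature <- gp$out
    out$cache <- caches
  }
  out
}

resnetBackward <- function(params, cfg, cache, dLogits = NULL, dFeature = NULL) {
  grads <- list()
  if (!is.null(dLogits)) {
    fb <- nnLinearBwd(matrix(dLogits, 1), matrix(cache$feature, 1), params$fc)
    grads$fc <- fb$grads
    dFeature <- fb$dx[1, ]
  }
  dh <- globalAvgPoolBwd(dFeature, cache$gap)
  gstages <- vector("list", 4)
  for (s in 4:1) {
    nb <- length(params$stages[[s]])
    gstages[[s]] <- vector("list", nb)
    for (b in nb:1) {
      bb <- resnetBlockBwd(dh, cache$stages[[s]][[b]],
                           params$stages[[s]][[b]], cfg)
      dh <- bb$dx
      gstages[[s]][[b]] <- bb$grads
    }
  }
  dmp <- maxPool3dBwd(dh, cache$stem$mp)
  drs <- reluBwd(dmp, cache$stem$r)
  bsb <- bnBwd(drs, cache$stem$b, params$stem$bn$g)
  csb <- conv3dBwd(bsb$dx, cache$stem$c, params$stem$conv$W)
  g <- list(stem = list(conv = list(W = csb$dW),
                        bn = list(g = bsb$dg, b = bsb$db)),
            stages = gstages)
  if (!is.null(grads$fc)) g$fc <- grads$fc
  g[names(params)]
}

volumeToInput <- function(vol, channels = 1L) {
  a <- if (is(vol, "MedicalVolume")) voxels(vol) else vol
  x <- array(a, c(dim(a), 1L))
  if (channels > 1L) x <- array(rep(x, channels), c(dim(a), channels))
  x
}

#' @describeIn predictVolume 3D residual network: returns `logits` and the
#'   pooled `feature` vector.
setMethod("predictVolume", "ResNet3D", function(model, vol, ...) {
  x <- volumeToInput(vol, model@config$inChannels)
  f <- resnetForward(model@params, model@state, model@config, x)
  list(logits = f$logits, feature = f$feature)
})

# 2D slice encoder forward: slice matrix -> pooled feature (+ caches)
cnnEncoderForward <- function(encoder, sliceImage, training = FALSE,
                              needCache = FALSE) {
  x <- array(rep(sliceImage, 3L), c(1L, dim(sliceImage), 3L))
  f <- resnetForward(encoder@params, encoder@state, encoder@config, x,
                     training, needCache)
  f
}

#' @rdname countParams
setMethod("countParams", "ResNet3D", function(object)
  leafElementCount(object@params))

#' @rdname countParams
setMethod("countParams", "CNNEncoder", function(object)
  leafElementCount(object@params))

#' @describeIn computeSaliency 3D residual network: activation-times-gradient
#'   map at the last convolutional stage (`method = "gradcam3d"`), trilinearly
#'   interpolated to the input resolution. The gradient of the selected class
#'   score with respect to the last stage's activations flows through the
#'   global average pool and the affine head.
#' @param pooled use the channel-pooled weighting (see [gradCAM3D()]).
setMethod("computeSaliency", "ResNet3D", function(model, vol, classIndex = NULL,
                                                  pooled = FALSE, ...) {
  a <- if (is(vol, "MedicalVolume")) voxels(vol) else vol
  x <- volumeToInput(vol, model@config$inChannels)
  f <- resnetForward(model@params, model@state, model@config, x)
  if (is.null(classIndex)) classIndex <- which.max(f$logits) - 1L
  d <- dim(f$lastAct)
  nSpatial <- prod(d[1:3])
  w <- model@params$fc$W[, classIndex + 1L]
  grads <- array(rep(w, each = nSpatial), d) / nSpatial
  gradCAM3D(f$lastAct, grads, outShape = dim(a), pooled = pooled)
})
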
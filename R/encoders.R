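# 2D slice encoders: a vision transformer (classification token + optional
# register tokens, pre-norm blocks) returning the classification-token
# feature and its patch-attention grid, and a 2D residual network returning
# the post-pooling feature vector. Single-channel slices are replicated to
# three channels so externally obtained natural-image weights remain usable.

#' Vision-transformer encoder configuration
#'
#' Presets: `"vit_small"` (patch 14, embed 384, depth 12, heads 6 - the
#' standard small self-supervised backbone geometry), `"vit_base"` (patch 14,
#' embed 768, depth 12, heads 12), and `"tiny"` (side 32, patch 8, embed 64,
#' depth 2, heads 4), a desk-scale geometry that exercises every code path in
#' seconds and is used throughout the tests.
#'
#' @param preset optional preset name; explicit arguments override it.
#' @param side square input side in pixels; must be divisible by `patch`.
#' @param patch patch size in pixels.
#' @param embedDim token embedding dimension; divisible by `heads`.
#' @param depth number of Transformer blocks.
#' @param heads attention heads per block.
#' @param mlpRatio feed-forward width as a multiple of `embedDim`.
#' @param nRegisters number of register tokens (participate in attention but
#'   are excluded from the spatial attention map).
#' @param frozen if `TRUE` the encoder's parameters are excluded from
#'   training updates.
#' @return a list of class `"vitConfig"`.
#' @export
vitConfig <- function(preset = NULL, side = NULL, patch = NULL, embedDim = NULL,
                      depth = NULL, heads = NULL, mlpRatio = 4,
                      nRegisters = 0L, frozen = FALSE) {
  base <- switch(preset %||% "custom",
    vit_small = list(side = 224L, patch = 14L, embedDim = 384L, depth = 12L, heads = 6L),
    vit_base  = list(side = 224L, patch = 14L, embedDim = 768L, depth = 12L, heads = 12L),
    tiny      = list(side = 32L, patch = 8L, embedDim = 64L, depth = 2L, heads = 4L),
    custom    = list(side = 224L, patch = 14L, embedDim = 384L, depth = 12L, heads = 6L))
  cfg <- list(family = "vit",
              side = as.integer(side %||% base$side),
              patch = as.integer(patch %||% base$patch),
              embedDim = as.integer(embedDim %||% base$embedDim),
              depth = as.integer(depth %||% base$depth),
              heads = as.integer(heads %||% base$heads),
              mlpRatio = mlpRatio, nRegisters = as.integer(nRegisters),
              frozen = isTRUE(frozen))
  if (cfg$side %% cfg$patch != 0L)
    stop("input side ", cfg$side, " is not divisible by patch size ", cfg$patch)
  if (cfg$embedDim %% cfg$heads != 0L)
    stop("embedDim must be divisible by heads")
  cfg$grid <- cfg$side %/% cfg$patch
  class(cfg) <- c("vitConfig", "list")
  cfg
}

vitParamShapes <- function(cfg) {
  d <- cfg$embedDim
  blk <- list(ln1 = list(g = d, b = d),
              attn = list(qkv = list(W = c(d, 3 * d), b = 3 * d),
                          proj = list(W = c(d, d), b = d)),
              ln2 = list(g = d, b = d),
              fc1 = list(W = c(d, cfg$mlpRatio * d), b = cfg$mlpRatio * d),
              fc2 = list(W = c(cfg$mlpRatio * d, d), b = d))
  shapes <- list(
    patchEmbed = list(W = c(cfg$patch^2 * 3L, d), b = d),
    posEmbed = c(1L + cfg$grid^2, d),
    clsToken = d,
    blocks = rep(list(blk), cfg$depth),
    lnFinal = list(g = d, b = d))
  if (cfg$nRegisters > 0L) shapes$registers <- c(cfg$nRegisters, d)
  shapes
}

shapeCount <- function(shapes) {
  if (is.list(shapes)) sum(vapply(shapes, shapeCount, numeric(1)))
  else prod(shapes)
}

materializeShapes <- function(shapes, sd = 0.02) {
  mapParams(function(dm) {
    n <- prod(dm)
    v <- stats::rnorm(n, sd = sd)
    if (length(dm) > 1L) array(v, dm) else v
  }, shapes)
}

#' Construct a slice encoder from a configuration
#'
#' Parameters are initialized from a seeded normal distribution (sd 0.02);
#' layer-norm gains are set to one and all biases to zero.
#'
#' @param cfg a [vitConfig()] or [cnnConfig()].
#' @param seed integer seed for the initialization.
#' @return a [ViTEncoder-class] or [CNNEncoder-class].
#' @examples
#' enc <- buildEncoder(vitConfig("tiny"), seed = 1)
#' enc
#' @export
buildEncoder <- function(cfg, seed = 1L) {
  if (inherits(cfg, "vitConfig")) {
    params <- withSeed(seed, materializeShapes(vitParamShapes(cfg)))
    params <- vitNeutralize(params)
    ViTEncoder(config = cfg, params = params)
  } else if (inherits(cfg, "cnnConfig")) {
    buildCNNEncoder(cfg, seed)
  } else stop("unknown encoder configuration")
}

# set layer norms to identity and biases to zero after random init
vitNeutralize <- function(params) {
  fix <- function(p) {
    if (!is.list(p)) return(p)
    nm <- names(p)
    if (identical(sort(nm), c("b", "g"))) { p$g[] <- 1; p$b[] <- 0; return(p) }
    if ("b" %in% nm && "W" %in% nm) { p$b[] <- 0 }
    lapply(p, fix)
  }
  fix(params)
}

# flatten a square slice into patch tokens: rows ordered patch-row fastest,
# columns the flattened (row, col) pixels replicated to three channels.
patchify <- function(img, patch) {
  side <- nrow(img)
  g <- side %/% patch
  a <- array(img, c(patch, g, patch, g))
  a <- aperm(a, c(2, 4, 1, 3))            # (pr, pc, i, j)
  P <- matrix(a, g * g, patch * patch)
  cbind(P, P, P)
}

vitForward <- function(params, cfg, img, needCache = FALSE) {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop("slice image must be a square matrix")
  if (nrow(img) != cfg$side)
    stop("slice side ", nrow(img), " does not match the configured side ",
         cfg$side)
  if (nrow(img) %% cfg$patch != 0L)
    stop("slice side ", nrow(img), " is not divisible by patch size ", cfg$patch)
  g <- cfg$grid
  R <- cfg$nRegisters
  P <- patchify(img, cfg$patch)
  pe <- nnLinearFwd(P, params$patchEmbed)
  tok <- pe$out + params$posEmbed[-1, , drop = FALSE]
  cls <- params$clsToken + params$posEmbed[1, ]
  x <- if (R > 0L) rbind(matrix(cls, 1), params$registers, tok)
       else rbind(matrix(cls, 1), tok)
  caches <- if (needCache) vector("list", cfg$depth) else NULL
  attnLast <- NULL
  for (l in seq_len(cfg$depth)) {
    bf <- nnBlockFwd(x, params$blocks[[l]], cfg$heads)
    x <- bf$out
    if (l == cfg$depth) attnLast <- bf$attn
    if (needCache) caches[[l]] <- bf$cache
  }
  lf <- nnLayerNormFwd(x, params$lnFinal)
  feature <- lf$out[1, ]
  # classification-token attention over patch tokens: per head drop the
  # classification/register columns, renormalize, then average heads
  clsRows <- do.call(rbind, lapply(attnLast, function(A) A[1, ]))
  pa <- extractClsAttention(clsRows, dropCols = seq_len(1L + R))
  list(feature = feature, patchAttention = matrix(pa, g, g),
       cache = if (needCache) list(P = P, blocks = caches, ln = lf$cache,
                                   nTok = nrow(x)) else NULL)
}

vitBackward <- function(params, cfg, cache, dFeature) {
  d <- cfg$embedDim
  R <- cfg$nRegisters
  dOut <- matrix(0, cache$nTok, d)
  dOut[1, ] <- dFeature
  lb <- nnLayerNormBwd(dOut, cache$ln, params$lnFinal)
  dx <- lb$dx
  gblocks <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    bb <- nnBlockBwd(dx, cache$blocks[[l]], params$blocks[[l]], cfg$heads)
    dx <- bb$dx
    gblocks[[l]] <- bb$grads
  }
  dCls <- dx[1, ]
  dTok <- dx[(2L + R):cache$nTok, , drop = FALSE]
  peb <- nnLinearBwd(dTok, cache$P, params$patchEmbed)
  dPos <- rbind(matrix(dCls, 1), dTok)
  grads <- list(patchEmbed = peb$grads, posEmbed = dPos, clsToken = dCls,
                blocks = gblocks, lnFinal = lb$grads)
  if (R > 0L) grads$registers <- dx[1L + seq_len(R), , drop = FALSE]
  grads[names(params)]
}

#' @describeIn encodeSlice vision-transformer encoder: classification-token
#'   feature plus the g x g patch-attention grid.
setMethod("encodeSlice", "ViTEncoder", function(encoder, sliceImage) {
  f <- vitForward(encoder@params, encoder@config, sliceImage)
  SliceEncoding(feature = f$feature, patchAttention = f$patchAttention)
})

#' @describeIn encodeSlice 2D residual-network encoder: post-pooling feature
#'   vector; no patch attention.
setMethod("encodeSlice", "CNNEncoder", function(encoder, sliceImage) {
  f <- cnnEncoderForward(encoder, sliceImage)
  SliceEncoding(feature = f$feature, patchAttention = NULL)
})

#' Encode every slice of a volume
#'
#' @param encoder a [ViTEncoder-class] or [CNNEncoder-class].
#' @param vol a [MedicalVolume-class] or 3D array (slice, row, col).
#' @return a [SliceFeatureSet-class].
#' @export
encodeVolume <- function(encoder, vol) {
  a <- if (is(vol, "MedicalVolume")) voxels(vol) else vol
  n <- dim(a)[1]
  encs <- lapply(seq_len(n), function(i) encodeSlice(encoder, a[i, , ]))
  feats <- do.call(rbind, lapply(encs, function(e) e@feature))
  maps <- lapply(encs, function(e) e@patchAttention)
  if (any(vapply(maps, is.null, logical(1)))) maps <- list()
  SliceFeatureSet(features = feats, patchMaps = maps,
                  sliceIds = seq_len(n) - 1L)
}

#' @rdname countParams
setMethod("countParams", "ViTEncoder", function(object)
  leafElementCount(object@params))

#' @rdname countParams
setMethod("countParams", "ANY", function(object) {
  if (inherits(object, "vitConfig")) return(shapeCount(vitParamShapes(object)))
  if (inherits(object, "aggregatorConfig")) return(shapeCount(aggParamShapes(object)))
  if (inherits(object, "resnetConfig")) return(shapeCount(resnetParamShapes(object)))
  if (inherits(object, "cnnConfig")) return(shapeCount(resnetParamShapes(object)))
  stop("countParams: unsupported object of class ", class(object)[1])
})

#' Parameter count rounded to the nearest million
#'
#' Reporting helper: models of this family are conventionally described by
#' their parameter count in millions.
#'
#' @param object anything [countParams()] accepts.
#' @return numeric, `round(countParams(object) / 1e6)`.
#' @examples
#' paramsMillions(vitConfig("vit_base"))  # 86
#' @export
paramsMillions <- function(object) round(countParams(object) / 1e6)
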
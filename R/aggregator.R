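# Slice-level aggregation and classification: a single-layer Transformer with
# a learned classification token (the reference architecture), its additive
# positional-embedding variant, and the linear / averaging ablations.

#' Slice-aggregator configuration
#'
#' `kind = "transformer"` prepends a learned classification token to the N
#' slice features, applies one pre-norm Transformer encoder layer, and maps
#' the classification-token output through an affine head to the class
#' logits; without positional embeddings its logits are invariant to slice
#' permutations. `"transformer_adpe"` additionally adds a learned embedding
#' per slice index (order-aware). `"linear"` flattens the N x d feature
#' matrix and applies a single affine map. `"average"` feeds the mean feature
#' vector through the affine head.
#'
#' Head count and feed-forward width default by embedding dimension:
#' 384 maps to 12 heads / 384 channels, 512 to 16 / 512, 768 to 16 / 768
#' (head dimension stays >= 32 and the single-layer transformer part lands at
#' about one million parameters for the 384-dim encoder); other embedding
#' dimensions default to 4 heads and a feed-forward width equal to the
#' embedding.
#'
#' @param kind one of `"transformer"`, `"transformer_adpe"`, `"linear"`,
#'   `"average"`.
#' @param embedDim slice-feature dimension.
#' @param nSlices number of slices per volume (required by the `linear` and
#'   `transformer_adpe` kinds; the others accept any slice count at run
#'   time).
#' @param nClasses number of classes (default 2).
#' @param heads,ffnDim transformer geometry overrides.
#' @param layers number of encoder layers; fixed at 1.
#' @return a list of class `"aggregatorConfig"`.
#' @export
aggregatorConfig <- function(kind = c("transformer", "transformer_adpe",
                                      "linear", "average"),
                             embedDim, nSlices, nClasses = 2L,
                             heads = NULL, ffnDim = NULL, layers = 1L) {
  kind <- match.arg(kind)
  if (layers != 1L) stop("the slice transformer uses exactly one layer")
  defaults <- switch(as.character(embedDim),
                     "384" = c(12L, 384L), "512" = c(16L, 512L),
                     "768" = c(16L, 768L), c(4L, as.integer(embedDim)))
  cfg <- list(kind = kind, embedDim = as.integer(embedDim),
              nSlices = as.integer(nSlices), nClasses = as.integer(nClasses),
              heads = as.integer(heads %||% defaults[1]),
              ffnDim = as.integer(ffnDim %||% defaults[2]), layers = 1L)
  if (cfg$embedDim %% cfg$heads != 0L)
    stop("embedDim must be divisible by heads")
  class(cfg) <- c("aggregatorConfig", "list")
  cfg
}

aggParamShapes <- function(cfg) {
  d <- cfg$embedDim
  switch(cfg$kind,
    transformer = ,
    transformer_adpe = {
      s <- list(clsToken = d,
                block = list(ln1 = list(g = d, b = d),
                             attn = list(qkv = list(W = c(d, 3 * d), b = 3 * d),
                                         proj = list(W = c(d, d), b = d)),
                             ln2 = list(g = d, b = d),
                             fc1 = list(W = c(d, cfg$ffnDim), b = cfg$ffnDim),
                             fc2 = list(W = c(cfg$ffnDim, d), b = d)),
                lnFinal = list(g = d, b = d),
                head = list(W = c(d, cfg$nClasses), b = cfg$nClasses))
      if (cfg$kind == "transformer_adpe") s$posEmbed <- c(cfg$nSlices, d)
      s
    },
    linear = list(head = list(W = c(cfg$nSlices * d, cfg$nClasses),
                              b = cfg$nClasses)),
    average = list(head = list(W = c(d, cfg$nClasses), b = cfg$nClasses)))
}

#' Construct a slice aggregator
#'
#' Weights and the classification token are initialized from a seeded normal
#' distribution (sd 0.02); layer norms start at identity, biases at zero.
#'
#' @param cfg an [aggregatorConfig()].
#' @param seed integer seed.
#' @return a [SliceAggregator-class].
#' @export
buildAggregator <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "aggregatorConfig"))
  params <- withSeed(seed, materializeShapes(aggParamShapes(cfg)))
  params <- vitNeutralize(params)
  SliceAggregator(config = cfg, params = params)
}

aggForward <- function(params, cfg, feats, needCache = FALSE) {
  if (cfg$kind %in% c("linear", "transformer_adpe") &&
      nrow(feats) != cfg$nSlices)
    stop("dimension mismatch: aggregator configured for ", cfg$nSlices,
         " slices but received ", nrow(feats))
  if (ncol(feats) != cfg$embedDim)
    stop("dimension mismatch: aggregator embedDim ", cfg$embedDim,
         " but features have ", ncol(feats), " columns")
  switch(cfg$kind,
    linear = {
      v <- matrix(as.vector(feats), 1)
      hf <- nnLinearFwd(v, params$head)
      list(logits = hf$out[1, ], sliceAttention = NULL,
           cache = if (needCache) list(v = v, n = nrow(feats)) else NULL)
    },
    average = {
      m <- matrix(colMeans(feats), 1)
      hf <- nnLinearFwd(m, params$head)
      list(logits = hf$out[1, ], sliceAttention = NULL,
           cache = if (needCache) list(m = m, n = nrow(feats)) else NULL)
    },
    {
      x <- rbind(matrix(params$clsToken, 1), feats)
      if (cfg$kind == "transformer_adpe")
        x[-1, ] <- x[-1, ] + params$posEmbed
      bf <- nnBlockFwd(x, params$block, cfg$heads)
      lf <- nnLayerNormFwd(bf$out, params$lnFinal)
      hf <- nnLinearFwd(lf$out[1, , drop = FALSE], params$head)
      clsRows <- do.call(rbind, lapply(bf$attn, function(A) A[1, ]))
      sa <- extractClsAttention(clsRows, dropCols = 1L)
      list(logits = hf$out[1, ], sliceAttention = sa,
           cache = if (needCache) list(block = bf$cache, ln = lf$cache,
                                       lnOut1 = lf$out[1, , drop = FALSE],
                                       nTok = nrow(x)) else NULL)
    })
}

aggBackward <- function(params, cfg, cache, dLogits) {
  dl <- matrix(dLogits, 1)
  switch(cfg$kind,
    linear = {
      hb <- nnLinearBwd(dl, cache$v, params$head)
      list(dFeats = matrix(hb$dx, cache$n),
           grads = list(head = hb$grads))
    },
    average = {
      hb <- nnLinearBwd(dl, cache$m, params$head)
      list(dFeats = matrix(rep(hb$dx / cache$n, each = cache$n), cache$n),
           grads = list(head = hb$grads))
    },
    {
      hb <- nnLinearBwd(dl, cache$lnOut1, params$head)
      dOut <- matrix(0, cache$nTok, cfg$embedDim)
      dOut[1, ] <- hb$dx
      lb <- nnLayerNormBwd(dOut, cache$ln, params$lnFinal)
      bb <- nnBlockBwd(lb$dx, cache$block, params$block, cfg$heads)
      dFeats <- bb$dx[-1, , drop = FALSE]
      grads <- list(clsToken = bb$dx[1, ], block = bb$grads,
                    lnFinal = lb$grads, head = hb$grads)
      if (cfg$kind == "transformer_adpe") grads$posEmbed <- dFeats
      list(dFeats = dFeats, grads = grads[names(params)])
    })
}

#' @describeIn aggregateAndClassify aggregate a [SliceFeatureSet-class] with
#'   any aggregator kind.
setMethod("aggregateAndClassify", "SliceAggregator", function(aggregator, feats) {
  f <- if (is(feats, "SliceFeatureSet")) feats@features else feats
  out <- aggForward(aggregator@params, aggregator@config, f)
  ClassifierOutput(logits = out$logits, sliceAttention = out$sliceAttention)
})

#' @rdname countParams
setMethod("countParams", "SliceAggregator", function(object)
  leafElementCount(object@params))
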
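# The slice-transformer classifier: a 2D slice encoder feeding a slice
# aggregator, with joint forward/backward passes for end-to-end training and
# attention flow for saliency.

#' Build a slice-transformer model
#'
#' @param encoder a [ViTEncoder-class] or [CNNEncoder-class] (or its config).
#' @param aggregator a [SliceAggregator-class] (or its config); its
#'   `embedDim` must match the encoder's feature dimension.
#' @param seed seed used when configs rather than built components are given.
#' @return an [MSTModel-class].
#' @examples
#' m <- buildMST(vitConfig("tiny"), aggregatorConfig("transformer",
#'               embedDim = 64, nSlices = 16), seed = 1)
#' paramsMillions(m)
#' @export
buildMST <- function(encoder, aggregator, seed = 1L) {
  if (inherits(encoder, c("vitConfig", "cnnConfig")))
    encoder <- buildEncoder(encoder, seed)
  if (inherits(aggregator, "aggregatorConfig"))
    aggregator <- buildAggregator(aggregator, seed + 1L)
  encDim <- if (is(encoder, "ViTEncoder")) encoder@config$embedDim
            else encoder@config$embedDim
  if (encDim != aggregator@config$embedDim)
    stop("encoder feature dimension (", encDim,
         ") does not match aggregator embedDim (",
         aggregator@config$embedDim, ")")
  MSTModel(encoder = encoder, aggregator = aggregator)
}

#' @rdname countParams
setMethod("countParams", "MSTModel", function(object)
  countParams(object@encoder) + countParams(object@aggregator))

#' @describeIn predictVolume slice transformer: encodes every slice,
#'   aggregates, and returns `logits`, `prob` (softmax), `sliceAttention`
#'   and per-slice `patchMaps` (transformer aggregators).
setMethod("predictVolume", "MSTModel", function(model, vol, ...) {
  feats <- encodeVolume(model@encoder, vol)
  out <- aggForward(model@aggregator@params, model@aggregator@config,
                    feats@features)
  z <- out$logits - max(out$logits)
  list(logits = out$logits, prob = exp(z) / sum(exp(z)),
       sliceAttention = out$sliceAttention,
       patchMaps = if (length(feats@patchMaps)) feats@patchMaps else NULL)
})

# forward + backward of the full model for one labelled volume;
# returns loss, softmax probabilities, and gradients shaped like getParams()
mstGrad <- function(model, volArray, label) {
  enc <- model@encoder
  agg <- model@aggregator
  frozen <- isTRUE(enc@config$frozen)
  n <- dim(volArray)[1]
  caches <- vector("list", n)
  feats <- matrix(0, n, agg@config$embedDim)
  for (i in seq_len(n)) {
    if (is(enc, "ViTEncoder")) {
      f <- vitForward(enc@params, enc@config, volArray[i, , ],
                      needCache = !frozen)
    } else {
      f <- cnnEncoderForward(enc, volArray[i, , ], training = FALSE,
                             needCache = !frozen)
    }
    feats[i, ] <- f$feature
    caches[[i]] <- f$cache
  }
  af <- aggForward(agg@params, agg@config, feats, needCache = TRUE)
  ce <- nnCrossEntropy(af$logits, label)
  ab <- aggBackward(agg@params, agg@config, af$cache, ce$dlogits)
  encGrads <- NULL
  if (!frozen) {
    for (i in seq_len(n)) {
      gi <- if (is(enc, "ViTEncoder"))
        vitBackward(enc@params, enc@config, caches[[i]], ab$dFeats[i, ])
      else
        resnetBackward(enc@params, enc@config, caches[[i]],
                       dFeature = ab$dFeats[i, ])
      encGrads <- if (is.null(encGrads)) gi else addParams(encGrads, gi)
    }
  }
  list(loss = ce$loss, prob = ce$prob,
       grads = list(encoder = encGrads, aggregator = ab$grads))
}

resnet3dGrad <- function(model, volArray, label) {
  x <- array(volArray, c(dim(volArray), 1L))
  if (model@config$inChannels > 1L)
    x <- array(rep(x, model@config$inChannels),
               c(dim(volArray), model@config$inChannels))
  f <- resnetForward(model@params, model@state, model@config, x,
                     training = TRUE, needCache = TRUE)
  ce <- nnCrossEntropy(f$logits, label)
  g <- resnetBackward(model@params, model@config, f$cache, dLogits = ce$dlogits)
  list(loss = ce$loss, prob = ce$prob, grads = g, state = f$state)
}

# trainable parameters of a model as one nested list (frozen encoders are
# excluded, so the optimizer never touches them)
getParams <- function(model) {
  if (is(model, "MSTModel")) {
    p <- list(aggregator = model@aggregator@params)
    if (!isTRUE(model@encoder@config$frozen)) p$encoder <- model@encoder@params
    p
  } else if (is(model, "ResNet3D")) model@params
  else stop("unsupported model")
}

setParams <- function(model, params) {
  if (is(model, "MSTModel")) {
    model@aggregator@params <- params$aggregator
    if (!is.null(params$encoder)) model@encoder@params <- params$encoder
    model
  } else if (is(model, "ResNet3D")) {
    model@params <- params
    model
  } else stop("unsupported model")
}

modelGradientsOnce <- function(model, volArray, label) {
  if (is(model, "MSTModel")) {
    g <- mstGrad(model, volArray, label)
    gp <- list(aggregator = g$grads$aggregator)
    if (!isTRUE(model@encoder@config$frozen)) gp$encoder <- g$grads$encoder
    list(loss = g$loss, prob = g$prob, grads = gp, model = model)
  } else if (is(model, "ResNet3D")) {
    g <- resnet3dGrad(model, volArray, label)
    model@state <- g$state
    list(loss = g$loss, prob = g$prob, grads = g$grads, model = model)
  } else stop("unsupported model")
}

# probability of the positive class (index 1) for each volume in a list
scoreVolumes <- function(model, volumes) {
  vapply(volumes, function(v) {
    a <- if (is(v, "MedicalVolume")) voxels(v) else v
    p <- predictVolume(model, a)
    if (is.null(p$prob)) {
      z <- p$logits - max(p$logits)
      p$prob <- exp(z) / sum(exp(z))
    }
    p$prob[2]
  }, numeric(1))
}
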
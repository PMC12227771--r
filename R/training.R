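# Training recipe: seeded stochastic augmentation, class-balanced sampling
# weights, AdamW optimization of the cross-entropy loss, and early stopping on
# validation AUC with best-checkpoint selection.

#' Training configuration
#'
#' Defaults follow the reference recipe: batch size 2, AdamW with weight
#' decay 1e-2, early-stopping patience of 50 epochs on validation AUC. The
#' conventional learning rates are 1e-4 for the 3D residual network, 1e-5
#' for the slice transformer on CNN features and 1e-6 for the slice
#' transformer on pretrained vision-transformer features; when `lr` is `NULL`
#' it is resolved per model by those rules at `trainModel()` time (randomly
#' initialized desk-scale models train with an explicit, larger `lr`).
#'
#' Augmentation magnitudes (in-plane rotation range +/-10 degrees, noise SD
#' 5% of the intensity range, each transform applied with probability 0.5)
#' are explicit choices, as is treating a tied validation AUC as no
#' improvement.
#'
#' @param batchSize volumes per gradient step.
#' @param lr learning rate (`NULL` = resolve per model).
#' @param weightDecay decoupled weight decay.
#' @param patience epochs without strict validation-AUC improvement before
#'   stopping.
#' @param maxEpochs hard epoch cap.
#' @param seed seed governing sampling, augmentation and initialization of
#'   the optimizer run.
#' @param augmentations subset of `c("flip", "gaussian_noise", "rotation",
#'   "signal_inversion")`.
#' @param augmentProb per-transform application probability.
#' @param rotationRange in-plane rotation range in degrees.
#' @param noiseFraction noise SD as a fraction of the intensity range.
#' @param halfPrecision accepted for interface compatibility; computation in
#'   R is double precision and this flag is recorded but has no numerical
#'   effect.
#' @return a list of class `"trainConfig"`.
#' @export
trainConfig <- function(batchSize = 2L, lr = NULL, weightDecay = 1e-2,
                        patience = 50L, maxEpochs = 100L, seed = 1L,
                        augmentations = character(0), augmentProb = 0.5,
                        rotationRange = 10, noiseFraction = 0.05,
                        halfPrecision = FALSE) {
  if (!is.null(lr) && lr <= 0) stop("lr must be positive")
  if (patience < 1L) stop("patience must be >= 1")
  bad <- setdiff(augmentations,
                 c("flip", "gaussian_noise", "rotation", "signal_inversion"))
  if (length(bad)) stop("unknown augmentations: ", paste(bad, collapse = ", "))
  structure(list(batchSize = as.integer(batchSize), lr = lr,
                 weightDecay = weightDecay, patience = as.integer(patience),
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
                 augmentations = augmentations, augmentProb = augmentProb,
                 rotationRange = rotationRange, noiseFraction = noiseFraction,
                 halfPrecision = isTRUE(halfPrecision)),
            class = c("trainConfig", "list"))
}

defaultLR <- function(model) {
  if (is(model, "ResNet3D")) return(1e-4)
  if (is(model, "MSTModel")) {
    return(if (is(model@encoder, "ViTEncoder")) 1e-6 else 1e-5)
  }
  1e-4
}

# rotate one slice in-plane by `angle` degrees about the image centre,
# bilinear interpolation, `fill` outside the source image
rotateSlice <- function(m, angle, fill) {
  th <- angle * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r <- matrix(seq_len(nr), nr, nc) - cr
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  sr <- cos(th) * r - sin(th) * c + cr
  sc <- sin(th) * r + cos(th) * c + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- matrix(fill, nr, nc)
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    out
  }
  get(r0, c0) * (1 - fr) * (1 - fc) + get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc + get(r0 + 1, c0 + 1) * fr * fc
}

#' Seeded stochastic volume augmentation
#'
#' Applies, in order and each with probability `prob` (or always, with
#' `forceApply = TRUE`): a mirror flip along a randomly chosen axis, additive
#' Gaussian noise (SD = `noiseFraction` of the intensity range), an in-plane
#' rotation by a uniform angle in `+/-rotationRange` degrees with bilinear
#' interpolation, and signal inversion `v -> (max + min) - v` (an exact
#' involution). Deterministic for a fixed seed.
#'
#' @param vol a [MedicalVolume-class] or 3D array.
#' @param augmentations character subset of `c("flip", "gaussian_noise",
#'   "rotation", "signal_inversion")`.
#' @param seed integer seed.
#' @param prob per-transform application probability.
#' @param rotationRange degrees; `noiseFraction` fraction of intensity range.
#' @param noiseFraction see above.
#' @param forceApply apply every listed transform unconditionally.
#' @return object of the same type as `vol`.
#' @export
augmentVolume <- function(vol, augmentations, seed = 1L, prob = 0.5,
                          rotationRange = 10, noiseFraction = 0.05,
                          forceApply = FALSE) {
  isVol <- is(vol, "MedicalVolume")
  a <- if (isVol) voxels(vol) else vol
  a <- withSeed(seed, applyAugmentations(a, augmentations, prob,
                                         rotationRange, noiseFraction,
                                         forceApply))
  if (isVol) MedicalVolume(a, spacing = spacing(vol), modality = modality(vol))
  else a
}

# consumes the current RNG stream; used inside the training loop
applyAugmentations <- function(a, augmentations, prob = 0.5,
                               rotationRange = 10, noiseFraction = 0.05,
                               forceApply = FALSE) {
  doIt <- function() forceApply || stats::runif(1) < prob
  if ("flip" %in% augmentations && doIt()) {
    ax <- sample.int(3L, 1L)
    a <- switch(ax, a[rev(seq_len(dim(a)[1])), , , drop = FALSE],
                a[, rev(seq_len(dim(a)[2])), , drop = FALSE],
                a[, , rev(seq_len(dim(a)[3])), drop = FALSE])
  }
  if ("gaussian_noise" %in% augmentations && doIt()) {
    sd <- noiseFraction * diff(range(a))
    if (sd > 0) a <- a + array(stats::rnorm(length(a), 0, sd), dim(a))
  }
  if ("rotation" %in% augmentations && doIt()) {
    ang <- stats::runif(1, -rotationRange, rotationRange)
    fill <- min(a)
    for (i in seq_len(dim(a)[1])) a[i, , ] <- rotateSlice(a[i, , ], ang, fill)
  }
  if ("signal_inversion" %in% augmentations && doIt()) {
    a <- (max(a) + min(a)) - a
  }
  a
}

#' Class-balanced sampling weights
#'
#' Weight of class c proportional to `1 / count(c)`, so sampling with these
#' weights draws both classes at an expected 1:1 ratio regardless of
#' imbalance.
#'
#' @param labels vector of 0/1 labels; both classes must be present.
#' @return numeric per-sample weights.
#' @examples
#' classBalancedWeights(c(0, 0, 0, 1))
#' @export
classBalancedWeights <- function(labels) {
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present to balance sampling")
  unname(1 / as.numeric(tab[as.character(labels)]))
}

#' Assemble a labelled dataset from synthetic cases
#'
#' @param cases list of [SynthCase-class].
#' @return a list with `volumes` (list of arrays), `labels` (0/1 integer
#'   vector), `lesionSlices` and `lesionMasks` (per-case ground truth).
#' @export
casesToDataset <- function(cases) {
  list(volumes = lapply(cases, function(case) voxels(case@volume)),
       labels = vapply(cases, function(case) case@label, integer(1)),
       lesionSlices = lapply(cases, function(case) case@lesionSlices),
       lesionMasks = lapply(cases, function(case) case@lesionMask))
}

subsetDataset <- function(ds, idx) {
  list(volumes = ds$volumes[idx], labels = ds$labels[idx],
       lesionSlices = ds$lesionSlices[idx], lesionMasks = ds$lesionMasks[idx])
}

#' Train a model with weighted sampling and early stopping on validation AUC
#'
#' One epoch draws `length(trainSet$labels)` samples with replacement using
#' class-balanced weights, steps AdamW on the mean cross-entropy of each
#' batch, then scores the validation set. Training stops when `patience`
#' consecutive epochs fail to strictly exceed the best validation AUC (or at
#' `maxEpochs`); the returned model carries the parameters of the best epoch.
#' The run is deterministic for a fixed config seed.
#'
#' @param model an [MSTModel-class] or [ResNet3D-class].
#' @param trainSet,valSet datasets as produced by [casesToDataset()]; both
#'   classes must be present in each.
#' @param cfg a [trainConfig()].
#' @return a list: `model` (best checkpoint), `history`
#'   ([TrainHistory-class]), `bestValAUC`, and `checkpoint` (parameters plus
#'   run metadata for exact reload).
#' @export
trainModel <- function(model, trainSet, valSet, cfg = trainConfig()) {
  labels <- trainSet$labels
  if (length(unique(labels)) < 2L || length(unique(valSet$labels)) < 2L)
    stop("train and validation sets must each contain both classes")
  lr <- cfg$lr %||% defaultLR(model)
  w <- classBalancedWeights(labels)
  n <- length(labels)
  params <- getParams(model)
  opt <- adamInit(params)
  bestAUC <- -Inf
  bestParams <- params
  bestEpoch <- 0L
  sinceBest <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0), valAUC = numeric(0))
  withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$maxEpochs)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      epochLoss <- 0
      nb <- ceiling(n / cfg$batchSize)
      for (b in seq_len(nb)) {
        take <- idx[((b - 1L) * cfg$batchSize + 1L):min(b * cfg$batchSize, n)]
        bg <- NULL
        bl <- 0
        for (i in take) {
          a <- trainSet$volumes[[i]]
          if (length(cfg$augmentations))
            a <- applyAugmentations(a, cfg$augmentations, cfg$augmentProb,
                                    cfg$rotationRange, cfg$noiseFraction)
          g <- modelGradientsOnce(model, a, trainSet$labels[i])
          model <- g$model
          bg <- if (is.null(bg)) g$grads else addParams(bg, g$grads)
          bl <- bl + g$loss
        }
        if (!is.finite(bl))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        bg <- scaleParams(bg, 1 / length(take))
        st <- adamStep(params, bg, opt, lr, cfg$weightDecay)
        params <- st$params
        opt <- st$state
        model <- setParams(model, params)
        epochLoss <- epochLoss + bl
      }
      valScores <- scoreVolumes(model, valSet$volumes)
      vAUC <- aucScore(valScores, valSet$labels)
      hist <- rbind(hist, data.frame(epoch = epoch, loss = epochLoss / n,
                                     valAUC = vAUC))
      if (vAUC > bestAUC) {          # strict improvement; ties do not reset
        bestAUC <- vAUC
        bestParams <- params
        bestEpoch <- epoch
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= cfg$patience) break
      }
    }
  })
  model <- setParams(model, bestParams)
  history <- TrainHistory(epochs = hist, bestEpoch = bestEpoch,
                          stoppedEpoch = nrow(hist))
  list(model = model, history = history, bestValAUC = bestAUC,
       checkpoint = list(params = bestParams, bestValAUC = bestAUC,
                         bestEpoch = bestEpoch, lr = lr, seed = cfg$seed))
}

#' Replay the early-stopping rule on a validation-AUC sequence
#'
#' Pure bookkeeping helper (no training): given per-epoch validation AUCs,
#' returns when training would stop and which epoch's checkpoint would be
#' kept. Improvement means strictly exceeding the running best; ties do not
#' reset the patience counter.
#'
#' @param valAUCs numeric vector of per-epoch validation AUCs.
#' @param patience epochs without improvement tolerated before stopping.
#' @return list with `bestEpoch` and `stoppedEpoch`.
#' @examples
#' earlyStoppingReplay(c(0.6, 0.7, 0.65, 0.66), patience = 2)
#' @export
earlyStoppingReplay <- function(valAUCs, patience) {
  best <- -Inf
  bestEpoch <- 0L
  sinceBest <- 0L
  for (e in seq_along(valAUCs)) {
    if (valAUCs[e] > best) {
      best <- valAUCs[e]
      bestEpoch <- e
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= patience) return(list(bestEpoch = bestEpoch,
                                             stoppedEpoch = e))
    }
  }
  list(bestEpoch = bestEpoch, stoppedEpoch = length(valAUCs))
}
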
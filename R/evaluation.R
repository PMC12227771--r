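# Evaluation machinery: Mann-Whitney AUC, the fast DeLong test for paired
# AUCs (midrank formulation of the structural components), case-resampled
# bootstrap intervals, stratified group-aware splits, and automated
# localization proxies for saliency maps.

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' Equals the probability that a random positive outscores a random negative,
#' counting ties as one half; computed from midranks in O(n log n). Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return the AUC in `[0, 1]`.
#' @examples
#' aucScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  if (m == 0L || n == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

# structural components of the Mann-Whitney statistic via midranks:
# V10[i] = P(x_i > Y) + P(x_i = Y)/2 over negatives, V01 analogously
delongComponents <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  m <- length(x)
  n <- length(y)
  rAll <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  V10 <- (rAll[seq_len(m)] - rx) / n
  V01 <- 1 - (rAll[m + seq_len(n)] - ry) / m
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two score vectors on the same cases via the normal
#' approximation of the paired AUC difference, using the covariance of the
#' structural components (midrank formulation, O(n log n)). When the variance
#' of the difference is zero (e.g. identical score vectors) the statistic is
#' degenerate and `p = 1` is returned with `degenerate = TRUE`.
#'
#' @param scoresA,scoresB paired score vectors on identical cases.
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `aucA`, `aucB`, `z`, `p` (two-sided) and `degenerate`.
#' @export
deLongTest <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB) || length(scoresA) != length(labels))
    stop("scoresA, scoresB and labels must have equal length")
  a <- delongComponents(scoresA, labels)
  b <- delongComponents(scoresB, labels)
  m <- length(a$V10)
  n <- length(a$V01)
  if (m < 2L || n < 2L) stop("need at least two cases per class")
  v <- stats::var(a$V10 - b$V10) / m + stats::var(a$V01 - b$V01) / n
  d <- a$auc - b$auc
  if (v <= .Machine$double.eps) {
    return(list(aucA = a$auc, aucB = b$auc, z = 0, p = 1, degenerate = TRUE))
  }
  z <- d / sqrt(v)
  list(aucA = a$auc, aucB = b$auc, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Case-resampled bootstrap interval for the AUC
#'
#' Percentile 95% interval and standard deviation of the AUC over `nBoot`
#' seeded case resamples; replicates that draw a single class are redrawn.
#'
#' @inheritParams aucScore
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with `lo`, `hi`, `sd` and the replicate vector `aucs`.
#' @export
bootstrapCI <- function(scores, labels, nBoot = 1000L, seed = 1L) {
  nTotal <- length(scores)
  aucScore(scores, labels)   # validates both classes present
  aucs <- withSeed(seed, vapply(seq_len(nBoot), function(i) {
    repeat {
      idx <- sample.int(nTotal, nTotal, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    aucScore(scores[idx], labels[idx])
  }, numeric(1)))
  list(lo = unname(stats::quantile(aucs, 0.025)),
       hi = unname(stats::quantile(aucs, 0.975)),
       sd = stats::sd(aucs), aucs = aucs)
}

#' Stratified, group-aware train/validation/test split
#'
#' Splits samples into a training-validation and a test partition at the
#' given fractions, stratified by label, then subdivides the
#' training-validation part into training and validation (default 80/20).
#' When `groups` is supplied (e.g. patient identifiers for datasets with
#' several nodules per patient), all samples of a group stay in the same
#' partition; per-class counts in each partition land within one sample of
#' the target fraction. A split that cannot satisfy both constraints (for
#' instance a group holding all of one class) is rejected, naming the
#' offending group.
#'
#' @param labels 0/1 labels (at least two samples per class).
#' @param groups optional grouping key, same length as `labels`.
#' @param fractions length-2 fractions for (train-validation, test).
#' @param valFraction fraction of the training-validation part used for
#'   validation.
#' @param seed integer seed; identical seeds give identical splits.
#' @return a [Split-class] of integer sample indices.
#' @export
stratifiedGroupSplit <- function(labels, groups = NULL,
                                 fractions = c(0.8, 0.2), valFraction = 0.2,
                                 seed = 1L) {
  labels <- as.integer(labels)
  if (min(table(labels)) < 2L) stop("need at least two samples per class")
  if (is.null(groups)) groups <- seq_along(labels)
  if (length(groups) != length(labels))
    stop("groups must match labels in length")
  groups <- as.character(groups)
  gl <- split(labels, groups)
  gPos <- vapply(gl, function(v) sum(v == 1L), integer(1))
  gNeg <- vapply(gl, function(v) sum(v == 0L), integer(1))
  withSeed(seed, {
    held <- selectGroups(names(gl), gPos, gNeg, fractions[2])
    rest <- setdiff(names(gl), held)
    val <- selectGroups(rest, gPos[rest], gNeg[rest], valFraction)
    train <- setdiff(rest, val)
    gidx <- split(seq_along(labels), groups)
    Split(trainIds = sort(unlist(gidx[train], use.names = FALSE)),
          valIds = sort(unlist(gidx[val], use.names = FALSE)),
          testIds = sort(unlist(gidx[held], use.names = FALSE)),
          seed = as.integer(seed))
  })
}

# Draw whole groups into a held-out partition so that each class's held-out
# count lands within one sample of round(n_class * fraction). Greedy over a
# shuffled group order, never splitting a group; a group whose class counts
# cannot be accommodated within that tolerance triggers rejection.
selectGroups <- function(gs, gPos, gNeg, fraction) {
  targetPos <- round(sum(gPos) * fraction)
  targetNeg <- round(sum(gNeg) * fraction)
  ord <- sample(gs)
  take <- character(0)
  pos <- 0L
  neg <- 0L
  for (g in ord) {
    if (pos >= targetPos && neg >= targetNeg) break
    if (pos + gPos[g] <= targetPos + 1L && neg + gNeg[g] <= targetNeg + 1L &&
        (gPos[g] > 0 && pos < targetPos || gNeg[g] > 0 && neg < targetNeg)) {
      take <- c(take, g)
      pos <- pos + gPos[g]
      neg <- neg + gNeg[g]
    }
  }
  if (abs(pos - targetPos) > 1L || abs(neg - targetNeg) > 1L) {
    off <- ord[which.max(gPos[ord] + gNeg[ord])]
    stop("cannot stratify the split within one sample of the target ",
         "fractions; offending group: ", off,
         " (", gPos[off], " positive / ", gNeg[off], " negative samples)")
  }
  take
}

#' Automated localization proxies for a saliency map
#'
#' Automated stand-ins for the two reader criteria "does the map highlight
#' the slice(s) containing the lesion" and "does it point to the lesion
#' core": `sliceHit` is true when the slice with the largest total saliency
#' mass is one of the lesion slices, and `lesionHit` when the global peak
#' voxel lies inside the lesion mask dilated by one voxel. Argmax ties break
#' towards the lowest index (column-major voxel order for the peak),
#' deterministically.
#'
#' @param x an [AttentionBundle-class], [SaliencyVolume-class] or nonnegative
#'   3D array (slice, row, col).
#' @param lesionSlices integer vector of 1-based lesion slice indices.
#' @param lesionMask binary array congruent with the map.
#' @return list with logicals `sliceHit` and `lesionHit`.
#' @export
localizationProxies <- function(x, lesionSlices, lesionMask) {
  vals <- if (is(x, "AttentionBundle")) x@combined
          else if (is(x, "SaliencyVolume")) x@values
          else x
  if (length(lesionSlices) == 0L || !any(lesionMask != 0))
    stop("empty ground truth: lesion slices and mask are required")
  if (!identical(dim(vals), dim(lesionMask)))
    stop("saliency map and lesion mask shapes differ")
  perSlice <- apply(vals, 1, sum)
  sliceHit <- which.max(perSlice) %in% lesionSlices
  peak <- which.max(vals)
  lesionHit <- dilateMask1(lesionMask)[peak]
  list(sliceHit = sliceHit, lesionHit = unname(lesionHit))
}

#' Evaluate a model on a labelled dataset
#'
#' Scores every volume, computes the AUC with a case-resampled bootstrap
#' interval, the confusion matrix at probability threshold 0.5, an optional
#' DeLong comparison against a reference model's scores on the same cases,
#' and (for slice-transformer models on datasets with ground truth)
#' slice/lesion localization-proxy rates over the positive cases.
#'
#' @param model an [MSTModel-class] or [ResNet3D-class].
#' @param dataset a dataset as from [casesToDataset()].
#' @param refScores optional reference-model scores on the same cases for a
#'   DeLong comparison.
#' @param nBoot bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @param localization compute localization proxies over positive cases
#'   (requires an attention-capable model and per-case ground truth).
#' @return an [EvalResult-class].
#' @export
evaluateModel <- function(model, dataset, refScores = NULL, nBoot = 1000L,
                          seed = 1L, localization = FALSE) {
  scores <- scoreVolumes(model, dataset$volumes)
  labels <- dataset$labels
  auc <- aucScore(scores, labels)
  ci <- bootstrapCI(scores, labels, nBoot, seed)
  pred <- as.integer(scores >= 0.5)
  confusion <- table(factor(labels, levels = 0:1),
                     factor(pred, levels = 0:1))
  confusion <- matrix(as.integer(confusion), 2, 2,
                      dimnames = list(truth = c("0", "1"),
                                      predicted = c("0", "1")))
  dp <- NA_real_
  if (!is.null(refScores)) dp <- deLongTest(scores, refScores, labels)$p
  sliceHitRate <- NA_real_
  lesionHitRate <- NA_real_
  if (localization) {
    pos <- which(labels == 1L)
    hits <- vapply(pos, function(i) {
      sal <- computeSaliency(model, dataset$volumes[[i]])
      pr <- localizationProxies(sal, dataset$lesionSlices[[i]],
                                dataset$lesionMasks[[i]])
      c(pr$sliceHit, pr$lesionHit)
    }, logical(2))
    sliceHitRate <- mean(hits[1, ])
    lesionHitRate <- mean(hits[2, ])
  }
  EvalResult(auc = auc, aucSD = ci$sd, ci95 = c(ci$lo, ci$hi), delongP = dp,
             confusion = confusion, sliceHitRate = sliceHitRate,
             lesionHitRate = lesionHitRate)
}
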
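# Internal numeric helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Linear interpolation of array `a` along `axis` at fractional 0-based
# positions `pos` (clamped to the valid range). Used by both grid resampling
# and attention-map upscaling; separable application gives bi-/trilinear
# interpolation.
interpAxis <- function(a, axis, pos) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  n <- d[axis]
  pos <- pmin(pmax(pos, 0), n - 1L)
  lo <- pmin(floor(pos), n - 1)
  hi <- pmin(lo + 1, n - 1)
  w <- pos - lo
  perm <- c(axis, seq_along(d)[-axis])
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  out <- m[lo + 1, , drop = FALSE] * (1 - w) + m[hi + 1, , drop = FALSE] * w
  newd <- d[perm]
  newd[1] <- length(pos)
  out <- array(out, dim = newd)
  aperm(out, order(perm))
}

# Resize an array to `outDim` with separable linear interpolation,
# align-corners convention (endpoints map to endpoints).
resizeLinear <- function(a, outDim) {
  d <- dim(a)
  stopifnot(length(d) == length(outDim))
  for (ax in seq_along(d)) {
    if (outDim[ax] == dim(a)[ax]) next
    n <- dim(a)[ax]
    pos <- if (n == 1L) rep(0, outDim[ax]) else seq(0, n - 1, length.out = outDim[ax])
    a <- interpAxis(a, ax, pos)
  }
  a
}

# Dilate a binary 3D mask by one voxel (26-neighbourhood box).
dilateMask1 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (ds in -1:1) for (dr in -1:1) for (dc in -1:1) {
    si <- pmin(pmax(seq_len(d[1]) + ds, 1L), d[1])
    ri <- pmin(pmax(seq_len(d[2]) + dr, 1L), d[2])
    ci <- pmin(pmax(seq_len(d[3]) + dc, 1L), d[3])
    out <- out | (mask[si, ri, ci] != 0)
  }
  out
}

# --- nested parameter-list helpers ------------------------------------------

# Apply a binary function leafwise over congruent nested lists of arrays.
mapParams <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(seq_along(a), function(i) mapParams(f, a[[i]]))
    else lapply(seq_along(a), function(i) mapParams(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else {
    if (is.null(b)) f(a) else f(a, b)
  }
}

zeroLike <- function(p) mapParams(function(x) x * 0, p)

# Sum of element counts across all leaves.
leafElementCount <- function(p) {
  if (is.list(p)) sum(vapply(p, leafElementCount, numeric(1))) else length(p)
}

# Accumulate: a + b leafwise.
addParams <- function(a, b) mapParams(`+`, a, b)
scaleParams <- function(a, s) mapParams(function(x) x * s, a)

paramsIdentical <- function(a, b) isTRUE(all.equal(a, b, tolerance = 0)) && identical(
  mapParams(function(x) dim(x) %||% length(x), a),
  mapParams(function(x) dim(x) %||% length(x), b))

`%||%` <- function(x, y) if (is.null(x)) y else x
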
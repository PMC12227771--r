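# Convolutional primitives in plain R: 3D convolution via an im2col gather
# and one BLAS matrix product, batch normalization, ReLU and max/average
# pooling, each with an exact backward pass. Arrays are laid out
# (depth, height, width, channel); 2D networks use depth 1 with depth-1
# kernels, so one code path serves both the 2D slice encoder and the 3D
# reference model.

padArray4 <- function(x, pad, value = 0) {
  if (all(pad == 0L)) return(x)
  d <- dim(x)
  out <- array(value, c(d[1:3] + 2L * pad, d[4]))
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3]), ] <- x
  out
}

# linear gather indices for im2col: K x L matrix of 1-based indices into the
# padded array, K = prod(kernel) * Cin, L = number of output positions
im2colIndex <- function(dimPadded, kernel, stride, cin) {
  Dp <- dimPadded[1]; Hp <- dimPadded[2]; Wp <- dimPadded[3]
  oD <- (Dp - kernel[1]) %/% stride[1] + 1L
  oH <- (Hp - kernel[2]) %/% stride[2] + 1L
  oW <- (Wp - kernel[3]) %/% stride[3] + 1L
  kOff <- outer(outer(outer(seq_len(kernel[1]) - 1L,
                            (seq_len(kernel[2]) - 1L) * Dp, `+`),
                      (seq_len(kernel[3]) - 1L) * Dp * Hp, `+`),
                (seq_len(cin) - 1L) * Dp * Hp * Wp, `+`)
  start <- outer(outer((seq_len(oD) - 1L) * stride[1],
                       (seq_len(oH) - 1L) * stride[2] * Dp, `+`),
                 (seq_len(oW) - 1L) * stride[3] * Dp * Hp, `+`)
  list(idx = outer(as.vector(kOff), as.vector(start), `+`) + 1L,
       outDim = c(oD, oH, oW))
}

# x: (D, H, W, Cin); w: (kd, kh, kw, Cin, Cout), no bias (batch norm follows)
conv3dFwd <- function(x, w, stride = c(1L, 1L, 1L), pad = c(0L, 0L, 0L),
                      needCache = FALSE) {
  kd <- dim(w)
  xp <- padArray4(x, pad)
  ii <- im2colIndex(dim(xp)[1:3], kd[1:3], stride, dim(x)[4])
  K <- prod(kd[1:4])
  Xcol <- matrix(xp[as.vector(ii$idx)], K)
  Wmat <- matrix(w, K)
  Y <- crossprod(Xcol, Wmat)
  list(out = array(Y, c(ii$outDim, kd[5])),
       cache = if (needCache) list(Xcol = Xcol, idx = ii$idx,
                                   dimPadded = dim(xp), pad = pad,
                                   inDim = dim(x)) else NULL)
}

conv3dBwd <- function(dy, cache, w) {
  kd <- dim(w)
  K <- prod(kd[1:4])
  dY <- matrix(dy, ncol = kd[5])
  Wmat <- matrix(w, K)
  dW <- array(cache$Xcol %*% dY, dim(w))
  dXcol <- Wmat %*% t(dY)
  dxp <- numeric(prod(cache$dimPadded))
  rs <- rowsum(as.vector(dXcol), as.vector(cache$idx))
  dxp[as.integer(rownames(rs))] <- rs
  dxp <- array(dxp, cache$dimPadded)
  p <- cache$pad
  d <- cache$inDim
  list(dx = dxp[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]),
                p[3] + seq_len(d[3]), , drop = FALSE],
       dW = dW)
}

# batch norm over the channel (last) axis of a single 4D activation
bnFwd <- function(x, g, b, state, training = FALSE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, ncol = d[4])
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, inv, `*`)
  out <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  list(out = array(out, d), state = state,
       cache = list(xhat = xhat, inv = inv, d = d, training = training))
}

bnBwd <- function(dy, cache, g) {
  d <- cache$d
  dm <- matrix(dy, ncol = d[4])
  xhat <- cache$xhat
  dg <- colSums(dm * xhat)
  db <- colSums(dm)
  dxhat <- sweep(dm, 2, g, `*`)
  if (cache$training) {
    n <- nrow(dm)
    dx <- sweep(dxhat - matrix(colMeans(dxhat), n, d[4], byrow = TRUE) -
                  sweep(xhat, 2, colMeans(dxhat * xhat), `*`),
                2, cache$inv, `*`)
  } else {
    dx <- sweep(dxhat, 2, cache$inv, `*`)
  }
  list(dx = array(dx, d), dg = dg, db = db)
}

reluFwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
reluBwd <- function(dy, cache) dy * cache

maxPool3dFwd <- function(x, kernel = c(3L, 3L, 3L), stride = c(2L, 2L, 2L),
                         pad = c(1L, 1L, 1L), needCache = FALSE) {
  d <- dim(x)
  xp <- padArray4(x, pad, value = -Inf)
  ii <- im2colIndex(dim(xp)[1:3], kernel, stride, 1L)
  spp <- prod(dim(xp)[1:3])
  out <- array(0, c(ii$outDim, d[4]))
  arg <- if (needCache) array(0L, c(ii$outDim, d[4])) else NULL
  for (ch in seq_len(d[4])) {
    v <- matrix(xp[, , , ch][as.vector(ii$idx)], nrow(ii$idx))
    best <- max.col(t(v), ties.method = "first")
    L <- ncol(v)
    sel <- (seq_len(L) - 1L) * nrow(v) + best
    out[, , , ch] <- array(v[sel], ii$outDim)
    if (needCache) arg[, , , ch] <- ii$idx[sel] + (ch - 1L) * spp
  }
  list(out = out,
       cache = if (needCache) list(arg = arg, dimPadded = dim(xp), pad = pad,
                                   inDim = d) else NULL)
}

maxPool3dBwd <- function(dy, cache) {
  dxp <- numeric(prod(cache$dimPadded))
  rs <- rowsum(as.vector(dy), as.vector(cache$arg))
  dxp[as.integer(rownames(rs))] <- rs
  dxp <- array(dxp, cache$dimPadded)
  p <- cache$pad
  d <- cache$inDim
  dxp[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3]), ,
      drop = FALSE]
}

globalAvgPoolFwd <- function(x) {
  d <- dim(x)
  list(out = colMeans(matrix(x, ncol = d[4])), cache = d)
}

globalAvgPoolBwd <- function(dy, cache) {
  n <- prod(cache[1:3])
  array(rep(dy / n, each = n), cache)
}
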
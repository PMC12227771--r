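# Minimal neural-network core: dense layers, layer normalization, GELU,
# multi-head self-attention and pre-norm Transformer encoder blocks, with
# exact hand-derived backward passes, plus decoupled-weight-decay Adam.
# Everything operates on plain matrices (tokens in rows) so a whole model is a
# nested list of parameter arrays; gradients mirror that structure.

nnInitLinear <- function(nin, nout, sd = 0.02) {
  list(W = matrix(stats::rnorm(nin * nout, sd = sd), nin, nout),
       b = numeric(nout))
}

nnLinearFwd <- function(x, p) {
  list(out = x %*% p$W + matrix(p$b, nrow(x), length(p$b), byrow = TRUE),
       cache = x)
}

nnLinearBwd <- function(dy, cache, p) {
  list(dx = dy %*% t(p$W),
       grads = list(W = crossprod(cache, dy), b = colSums(dy)))
}

nnInitLayerNorm <- function(d) list(g = rep(1, d), b = numeric(d))

nnLayerNormFwd <- function(x, p, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2, p$g, `*`)
  out <- sweep(out, 2, p$b, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

nnLayerNormBwd <- function(dy, cache, p) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, p$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, grads = list(g = dg, b = db))
}

nnGeluFwd <- function(x) list(out = x * stats::pnorm(x), cache = x)
nnGeluBwd <- function(dy, cache) dy * (stats::pnorm(cache) + cache * stats::dnorm(cache))

nnSoftmaxRows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

nnSoftmaxRowsBwd <- function(dy, y) (dy - rowSums(dy * y)) * y

nnInitAttention <- function(d, sd = 0.02) {
  list(qkv = nnInitLinear(d, 3 * d, sd), proj = nnInitLinear(d, d, sd))
}

# Multi-head self-attention over a T x d token matrix. Returns the attention
# tensor as a list of per-head T x T matrices (rows = query tokens).
nnAttnFwd <- function(x, p, heads) {
  d <- ncol(x)
  dh <- d %/% heads
  qkvf <- nnLinearFwd(x, p$qkv)
  qkv <- qkvf$out
  Q <- qkv[, 1:d, drop = FALSE]
  K <- qkv[, d + 1:d, drop = FALSE]
  V <- qkv[, 2 * d + 1:d, drop = FALSE]
  O <- matrix(0, nrow(x), d)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- (h - 1) * dh + 1:dh
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    A[[h]] <- nnSoftmaxRows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  prf <- nnLinearFwd(O, p$proj)
  list(out = prf$out, attn = A,
       cache = list(x = x, Q = Q, K = K, V = V, A = A, O = O, heads = heads, dh = dh))
}

nnAttnBwd <- function(dy, cache, p) {
  d <- ncol(cache$x)
  dh <- cache$dh
  prb <- nnLinearBwd(dy, cache$O, p$proj)
  dO <- prb$dx
  dQ <- matrix(0, nrow(dO), d); dK <- dQ; dV <- dQ
  for (h in seq_len(cache$heads)) {
    idx <- (h - 1) * dh + 1:dh
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dAh <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(Ah, dOh)
    dS <- nnSoftmaxRowsBwd(dAh, Ah) / sqrt(dh)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  dqkv <- cbind(dQ, dK, dV)
  qkvb <- nnLinearBwd(dqkv, cache$x, p$qkv)
  list(dx = qkvb$dx, grads = list(qkv = qkvb$grads, proj = prb$grads))
}

nnInitBlock <- function(d, ffn, sd = 0.02) {
  list(ln1 = nnInitLayerNorm(d),
       attn = nnInitAttention(d, sd),
       ln2 = nnInitLayerNorm(d),
       fc1 = nnInitLinear(d, ffn, sd),
       fc2 = nnInitLinear(ffn, d, sd))
}

# Pre-norm Transformer encoder block: x + attn(LN(x)), then x + MLP(LN(x)).
nnBlockFwd <- function(x, p, heads) {
  l1 <- nnLayerNormFwd(x, p$ln1)
  at <- nnAttnFwd(l1$out, p$attn, heads)
  x1 <- x + at$out
  l2 <- nnLayerNormFwd(x1, p$ln2)
  f1 <- nnLinearFwd(l2$out, p$fc1)
  g1 <- nnGeluFwd(f1$out)
  f2 <- nnLinearFwd(g1$out, p$fc2)
  list(out = x1 + f2$out, attn = at$attn,
       cache = list(l1 = l1$cache, at = at$cache, l2 = l2$cache,
                    f1 = f1$cache, g1 = g1$cache, f2 = f2$cache))
}

nnBlockBwd <- function(dy, cache, p, heads) {
  f2b <- nnLinearBwd(dy, cache$f2, p$fc2)
  dg <- nnGeluBwd(f2b$dx, cache$g1)
  f1b <- nnLinearBwd(dg, cache$f1, p$fc1)
  l2b <- nnLayerNormBwd(f1b$dx, cache$l2, p$ln2)
  dx1 <- dy + l2b$dx
  atb <- nnAttnBwd(dx1, cache$at, p$attn)
  l1b <- nnLayerNormBwd(atb$dx, cache$l1, p$ln1)
  list(dx = dx1 + l1b$dx,
       grads = list(ln1 = l1b$grads, attn = atb$grads, ln2 = l2b$grads,
                    fc1 = f1b$grads, fc2 = f2b$grads))
}

# --- loss ---------------------------------------------------------------------

# Cross-entropy on a logits vector; returns loss, probabilities, and dlogits.
nnCrossEntropy <- function(logits, label) {
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  d <- p
  d[label + 1L] <- d[label + 1L] - 1
  list(loss = -log(p[label + 1L]), prob = p, dlogits = d)
}

# --- AdamW --------------------------------------------------------------------

adamInit <- function(params) list(m = zeroLike(params), v = zeroLike(params), t = 0L)

# One decoupled-weight-decay Adam update; returns updated params and state.
adamStep <- function(params, grads, state, lr, weightDecay = 1e-2,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapParams(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- mapParams(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  upd <- mapParams(function(m, v) c1 * m / (sqrt(c2 * v) + eps), state$m, state$v)
  params <- mapParams(function(p, u) p - lr * u, params, upd)
  if (weightDecay > 0)
    params <- mapParams(function(p) p * (1 - lr * weightDecay), params)
  list(params = params, state = state)
}
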
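# Internal neural-network primitives.  Every *_fwd returns list(out, cache)
# and the matching *_bwd consumes (cache, dout) and returns gradients.
# Shapes: token stacks are kept as (B*T) x E matrices produced by flat2()
# (sample index varies fastest), so row indices of sample b are
# seq(b, by = B, length = T).

add_bias <- function(m, b) m + rep(b, each = nrow(m))

lin_fwd <- function(x, w, b) list(out = add_bias(x %*% w, b), x = x)

lin_bwd <- function(cache, w, dout) {
  list(dx = dout %*% t(w), dw = crossprod(cache$x, dout),
       db = colSums(dout))
}

gelu_raw <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}

gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

drop_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- .drop_mask(length(x), p)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

drop_bwd <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# layer norm over the trailing (embedding) axis of a rows x E matrix
ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = add_bias(xhat * rep(g, each = nrow(x)), b),
       xhat = xhat, inv = inv, g = g)
}

ln_bwd <- function(cache, dout) {
  dxhat <- dout * rep(cache$g, each = nrow(dout))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = colSums(dout * cache$xhat), db = colSums(dout))
}

# batch norm with per-channel statistics over (batch, band) pairs;
# x is B x C x F, gamma/beta length C, running stats in `run`
bn_fwd <- function(x, gamma, beta, run, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  m <- aperm(x, c(1L, 3L, 2L))
  dim(m) <- c(d[1L] * d[3L], d[2L])
  if (training) {
    if (d[1L] < 2L)
      stop("batch normalization needs batch >= 2 in training mode; ",
           "use eval mode or a larger batch", call. = FALSE)
    mu <- colMeans(m)
    xc <- m - rep(mu, each = nrow(m))
    v <- colMeans(xc^2)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
    run$seen <- TRUE
  } else {
    mu <- if (isTRUE(run$seen)) run$mean else numeric(d[2L])
    v <- if (isTRUE(run$seen)) run$var else rep(1, d[2L])
    xc <- m - rep(mu, each = nrow(m))
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = nrow(m))
  y <- add_bias(xhat * rep(gamma, each = nrow(m)), beta)
  dim(y) <- c(d[1L], d[3L], d[2L])
  list(out = aperm(y, c(1L, 3L, 2L)), xhat = xhat, inv = inv,
       gamma = gamma, dims = d, training = training, run = run)
}

bn_bwd <- function(cache, dout) {
  d <- cache$dims
  dm <- aperm(dout, c(1L, 3L, 2L))
  dim(dm) <- c(d[1L] * d[3L], d[2L])
  n <- nrow(dm)
  dxhat <- dm * rep(cache$gamma, each = n)
  if (cache$training) {
    mh <- rep(colMeans(dxhat), each = n)
    mxh <- rep(colMeans(dxhat * cache$xhat), each = n)
    dx <- rep(cache$inv, each = n) * (dxhat - mh - cache$xhat * mxh)
  } else {
    dx <- rep(cache$inv, each = n) * dxhat
  }
  dim(dx) <- c(d[1L], d[3L], d[2L])
  list(dx = aperm(dx, c(1L, 3L, 2L)),
       dgamma = colSums(dm * cache$xhat), dbeta = colSums(dm))
}

# one residual graph-convolution layer on a B x C x F stack:
#   S = P X W + X ; out = GELU(S)                      (default)
#   S = GELU(P X W) + X ; out = GELU(S)                (double_activation)
gcn_fwd <- function(x, prop, w, double_activation = FALSE) {
  px <- graph_mul(prop, x)
  z <- feat_mul(px, w)
  if (double_activation) {
    a <- gelu_raw(z)
    s <- a + x
  } else {
    s <- z + x
  }
  list(out = gelu_raw(s), px = px, z = z, s = s,
       double_activation = double_activation)
}

gcn_bwd <- function(cache, prop, w, dout) {
  ds <- dout * gelu_grad(cache$s)
  if (cache$double_activation) {
    dz <- ds * gelu_grad(cache$z)
  } else {
    dz <- ds
  }
  dw <- crossprod(flat2(cache$px), flat2(dz))
  dx <- ds + graph_mul(t(prop), feat_mul(dz, t(w)))
  list(dx = dx, dw = dw)
}

# multi-head scaled dot-product attention over T tokens per sample;
# x is (B*T) x E with B samples, weights pack all heads column-wise.
# The per-(sample, head) loops live in compiled code (src/mha.cpp); the
# dropout mask is drawn here so determinism flows from R's RNG.
mha_fwd <- function(x, b_size, t_size, p, heads, dk, dropout, training) {
  q <- add_bias(x %*% p$wq, p$bq)
  k <- add_bias(x %*% p$wk, p$bk)
  v <- add_bias(x %*% p$wv, p$bv)
  mask <- if (training && dropout > 0)
    .drop_mask(t_size * t_size * heads * b_size, dropout)
  else numeric(0)
  core <- .mha_core_fwd(q, k, v, b_size, t_size, heads, dk, mask)
  z <- add_bias(core$O %*% p$wo, p$bo)
  list(out = z, x = x, q = q, k = k, v = v, o = core$O, a3 = core$A,
       mask = mask, b_size = b_size, t_size = t_size, heads = heads,
       dk = dk)
}

mha_bwd <- function(cache, p, dz) {
  do_ <- dz %*% t(p$wo)
  core <- .mha_core_bwd(cache$q, cache$k, cache$v, cache$a3, do_,
                        cache$b_size, cache$t_size, cache$heads,
                        cache$dk, cache$mask)
  dx <- core$dQ %*% t(p$wq) + core$dK %*% t(p$wk) + core$dV %*% t(p$wv)
  list(dx = dx,
       dwq = crossprod(cache$x, core$dQ), dbq = colSums(core$dQ),
       dwk = crossprod(cache$x, core$dK), dbk = colSums(core$dK),
       dwv = crossprod(cache$x, core$dV), dbv = colSums(core$dV),
       dwo = crossprod(cache$o, dz), dbo = colSums(dz))
}

# attention matrices of one mha cache as a (T, T, heads, B) array
mha_attention_array <- function(mha) {
  a <- mha$a3
  dim(a) <- c(mha$t_size, mha$t_size, mha$heads, mha$b_size)
  a
}

# post-norm transformer encoder layer:
#   X1 = LN1(X + MHA(X)) ; out = LN2(X1 + FF(X1))
enc_fwd <- function(xf, b_size, t_size, p, heads, dk, dropout, training) {
  mha <- mha_fwd(xf, b_size, t_size, p, heads, dk, dropout, training)
  l1 <- ln_fwd(xf + mha$out, p$ln1g, p$ln1b)
  h_pre <- add_bias(l1$out %*% p$w1, p$b1)
  h_act <- gelu_raw(h_pre)
  dr <- drop_fwd(h_act, dropout, training)
  f2 <- add_bias(dr$out %*% p$w2, p$b2)
  l2 <- ln_fwd(l1$out + f2, p$ln2g, p$ln2b)
  list(out = l2$out, mha = mha, l1 = l1, h_pre = h_pre, dr = dr, l2 = l2)
}

enc_bwd <- function(cache, p, dout) {
  b2w <- ln_bwd(cache$l2, dout)
  dx1 <- b2w$dx
  ddr <- drop_bwd(cache$dr, dx1 %*% t(p$w2))
  dw2 <- crossprod(cache$dr$out, dx1)
  db2 <- colSums(dx1)
  dh_pre <- ddr * gelu_grad(cache$h_pre)
  dl1 <- dx1 + dh_pre %*% t(p$w1)
  dw1 <- crossprod(cache$l1$out, dh_pre)
  db1 <- colSums(dh_pre)
  b1w <- ln_bwd(cache$l1, dl1)
  mha_b <- mha_bwd(cache$mha, p, b1w$dx)
  dx <- b1w$dx + mha_b$dx
  list(dx = dx, grads = c(
    mha_b[c("dwq", "dbq", "dwk", "dbk", "dwv", "dbv", "dwo", "dbo")],
    list(dln1g = b1w$dg, dln1b = b1w$db, dw1 = dw1, db1 = db1,
         dw2 = dw2, db2 = db2, dln2g = b2w$dg, dln2b = b2w$db)))
}

# batch-mean attention matrices of one encoder cache: heads x T x T
enc_attention <- function(cache) {
  t_ <- cache$mha$t_size; h_ <- cache$mha$heads
  a <- cache$mha$a3
  dim(a) <- c(t_ * t_ * h_, cache$mha$b_size)
  m <- array(rowMeans(a), c(t_, t_, h_))
  aperm(m, c(3L, 1L, 2L))
}
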
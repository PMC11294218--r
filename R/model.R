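#' Model configuration
#'
#' Architecture hyperparameters.  Defaults follow the published setting:
#' embedding size 64, 2 encoders per attention stage, 6 attention heads
#' (per-head dimension `floor(64 / 6) = 10` with an output projection back
#' to 64), dropout 0.5, a two-linear-layer classifier with hidden size
#' equal to the embedding, and 2 residual graph-convolution layers of
#' width `num_bands`.
#'
#' @param num_channels number of electrodes C.
#' @param num_bands number of frequency bands F.
#' @param num_classes number of emotion classes.
#' @param embedding token embedding size E.
#' @param encoders encoders per attention stage (channel and band each).
#' @param heads attention heads; per-head dim is `floor(embedding / heads)`.
#' @param dropout dropout rate in `[0, 1)`, applied to attention weights,
#'   feed-forward activations and the classifier hidden layer.
#' @param classifier_hidden hidden width of the classifier.
#' @param gcn_layers number of residual graph-convolution layers.
#' @param use_gcn,use_dam ablation flags: drop the graph-convolution block
#'   (with its batch norm) and/or the dual-attention block.  Both `FALSE`
#'   is the linear-only variant.
#' @param single_self_loop forwarded to [normalize_propagation()].
#' @param double_activation apply GELU both inside the graph convolution
#'   and after the residual (the literal reading); default applies it once,
#'   after the residual.
#' @param positional add learned positional embeddings to channel and band
#'   tokens.
#' @return a `damgcn_config` list.
#' @export
damgcn_config <- function(num_channels, num_bands, num_classes,
                          embedding = 64L, encoders = 2L, heads = 6L,
                          dropout = 0.5, classifier_hidden = embedding,
                          gcn_layers = 2L, use_gcn = TRUE, use_dam = TRUE,
                          single_self_loop = FALSE,
                          double_activation = FALSE, positional = FALSE) {
  cfg <- list(num_channels = as.integer(num_channels),
              num_bands = as.integer(num_bands),
              num_classes = as.integer(num_classes),
              embedding = as.integer(embedding),
              encoders = as.integer(encoders), heads = as.integer(heads),
              dropout = dropout,
              classifier_hidden = as.integer(classifier_hidden),
              gcn_layers = as.integer(gcn_layers),
              use_gcn = isTRUE(use_gcn), use_dam = isTRUE(use_dam),
              single_self_loop = isTRUE(single_self_loop),
              double_activation = isTRUE(double_activation),
              positional = isTRUE(positional))
  with(cfg, {
    stopifnot(num_channels >= 1, num_bands >= 1, num_classes >= 2,
              embedding >= heads, heads >= 1, encoders >= 1,
              gcn_layers >= 1, classifier_hidden >= 1,
              dropout >= 0, dropout < 1)
  })
  cfg$dk <- cfg$embedding %/% cfg$heads
  cfg$hd <- cfg$dk * cfg$heads
  class(cfg) <- "damgcn_config"
  cfg
}

xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

init_encoder <- function(e, hd, ffw) {
  list(wq = xavier(e, hd), bq = numeric(hd),
       wk = xavier(e, hd), bk = numeric(hd),
       wv = xavier(e, hd), bv = numeric(hd),
       wo = xavier(hd, e), bo = numeric(e),
       ln1g = rep(1, e), ln1b = numeric(e),
       w1 = xavier(e, ffw), b1 = numeric(ffw),
       w2 = xavier(ffw, e), b2 = numeric(e),
       ln2g = rep(1, e), ln2b = numeric(e))
}

init_params <- function(cfg) {
  c_ <- cfg$num_channels; f_ <- cfg$num_bands; e_ <- cfg$embedding
  ffw <- 4L * e_
  p <- list()
  if (cfg$use_gcn) {
    p$bn_gamma <- rep(1, c_)
    p$bn_beta <- numeric(c_)
    p$gcn <- lapply(seq_len(cfg$gcn_layers), function(i) xavier(f_, f_))
  }
  if (cfg$use_dam) {
    p$ch_embed_w <- xavier(f_, e_); p$ch_embed_b <- numeric(e_)
    p$ch_embed_lng <- rep(1, e_); p$ch_embed_lnb <- numeric(e_)
    if (cfg$positional) p$ch_pos <- matrix(0, c_, e_)
    p$ch_enc <- lapply(seq_len(cfg$encoders),
                       function(i) init_encoder(e_, cfg$hd, ffw))
    p$ch_unembed_w <- xavier(e_, f_); p$ch_unembed_b <- numeric(f_)
    p$band_embed_w <- xavier(c_, e_); p$band_embed_b <- numeric(e_)
    p$band_embed_lng <- rep(1, e_); p$band_embed_lnb <- numeric(e_)
    if (cfg$positional) p$band_pos <- matrix(0, f_, e_)
    p$band_gate <- numeric(f_)
    p$band_enc <- lapply(seq_len(cfg$encoders),
                         function(i) init_encoder(e_, cfg$hd, ffw))
  }
  d_in <- if (cfg$use_dam) f_ * e_ else c_ * f_
  p$cls_w1 <- xavier(d_in, cfg$classifier_hidden)
  p$cls_b1 <- numeric(cfg$classifier_hidden)
  p$cls_w2 <- xavier(cfg$classifier_hidden, cfg$num_classes)
  p$cls_b2 <- numeric(cfg$num_classes)
  p
}

#' Create a model
#'
#' Initializes all trainable parameters (Xavier-uniform weights, zero
#' biases, zero band gate so the initial band proportions are exactly
#' uniform) from the current RNG state.
#'
#' @param config a [damgcn_config()].
#' @param graph an `electrode_graph` with a propagation matrix (only
#'   required when `use_gcn = TRUE`); its channel count must match the
#'   config.
#' @return a `damgcn_model`.
#' @export
damgcn_model <- function(config, graph = NULL) {
  stopifnot(inherits(config, "damgcn_config"))
  if (config$use_gcn) {
    if (is.null(graph) || is.null(graph$propagation))
      stop("use_gcn = TRUE requires a graph with a propagation matrix",
           call. = FALSE)
    if (nrow(graph$propagation) != config$num_channels)
      stop("graph has ", nrow(graph$propagation),
           " channels but config expects ", config$num_channels,
           call. = FALSE)
  }
  structure(list(config = config, graph = graph,
                 params = init_params(config),
                 bn_run = list(mean = numeric(config$num_channels),
                               var = rep(1, config$num_channels),
                               seen = FALSE)),
            class = "damgcn_model")
}

#' @export
print.damgcn_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat("<damgcn_model> C=", cfg$num_channels, " F=", cfg$num_bands,
      " E=", cfg$embedding, " heads=", cfg$heads, " encoders=",
      cfg$encoders, "x2  classes=", cfg$num_classes,
      "  [gcn=", cfg$use_gcn, ", dam=", cfg$use_dam, "]  ",
      format(np, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

# full forward pass; returns logits, caches for backward, updated batch
# norm running stats and (optionally) the attention trace
damgcn_fwd <- function(model, x, training = FALSE, collect_trace = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- dim(x)
  stopifnot(length(d) == 3L, d[2L] == cfg$num_channels,
            d[3L] == cfg$num_bands)
  b_ <- d[1L]; c_ <- cfg$num_channels; f_ <- cfg$num_bands
  e_ <- cfg$embedding
  drp <- if (training) cfg$dropout else 0
  caches <- list()
  bn_run <- model$bn_run

  if (cfg$use_gcn) {
    bn <- bn_fwd(x, p$bn_gamma, p$bn_beta, bn_run, training)
    bn_run <- bn$run
    caches$bn <- bn
    h <- bn$out
    caches$gcn <- vector("list", cfg$gcn_layers)
    for (l in seq_len(cfg$gcn_layers)) {
      g <- gcn_fwd(h, model$graph$propagation, p$gcn[[l]],
                   cfg$double_activation)
      caches$gcn[[l]] <- g
      h <- g$out
    }
  } else {
    h <- x
  }
  caches$gcn_out <- h

  trace <- if (collect_trace)
    list(channel_attention = list(), band_attention = list()) else NULL

  if (cfg$use_dam) {
    # channel tokens: each channel's band vector embedded to E
    xf <- flat2(h)
    emb <- lin_fwd(xf, p$ch_embed_w, p$ch_embed_b)
    tok <- emb$out
    if (cfg$positional)
      tok <- tok + p$ch_pos[rep(seq_len(c_), each = b_), , drop = FALSE]
    lnc <- ln_fwd(tok, p$ch_embed_lng, p$ch_embed_lnb)
    caches$ch_embed <- list(lin = emb, ln = lnc)
    tf <- lnc$out
    caches$ch_enc <- vector("list", cfg$encoders)
    for (i in seq_len(cfg$encoders)) {
      en <- enc_fwd(tf, b_, c_, p$ch_enc[[i]], cfg$heads, cfg$dk, drp,
                    training)
      caches$ch_enc[[i]] <- en
      tf <- en$out
      if (collect_trace)
        trace$channel_attention[[i]] <- enc_attention(en)
    }
    # back to C x F cells, then transpose to band tokens
    une <- lin_fwd(tf, p$ch_unembed_w, p$ch_unembed_b)
    caches$ch_unembed <- une
    u <- array(une$out, c(b_, c_, f_))
    bt <- flat2(aperm(u, c(1L, 3L, 2L)))         # (B*F) x C
    bemb <- lin_fwd(bt, p$band_embed_w, p$band_embed_b)
    btok <- bemb$out
    if (cfg$positional)
      btok <- btok + p$band_pos[rep(seq_len(f_), each = b_), ,
                                drop = FALSE]
    lnb <- ln_fwd(btok, p$band_embed_lng, p$band_embed_lnb)
    caches$band_embed <- list(lin = bemb, ln = lnb)
    # learnable softmax band gate scales each band's token
    gate_p <- softmax_vec(p$band_gate)
    gated <- lnb$out * rep(gate_p, each = b_)
    caches$gate <- list(p = gate_p, pre = lnb$out)
    tf <- gated
    caches$band_enc <- vector("list", cfg$encoders)
    for (i in seq_len(cfg$encoders)) {
      en <- enc_fwd(tf, b_, f_, p$band_enc[[i]], cfg$heads, cfg$dk, drp,
                    training)
      caches$band_enc[[i]] <- en
      tf <- en$out
      if (collect_trace)
        trace$band_attention[[i]] <- enc_attention(en)
    }
    z <- matrix(array(tf, c(b_, f_, e_)), b_, f_ * e_)
    if (collect_trace) trace$band_proportions <- gate_p
  } else {
    z <- matrix(h, b_, c_ * f_)
  }
  caches$z <- z

  l1 <- lin_fwd(z, p$cls_w1, p$cls_b1)
  act <- gelu_raw(l1$out)
  dr <- drop_fwd(act, drp, training)
  l2 <- lin_fwd(dr$out, p$cls_w2, p$cls_b2)
  caches$cls <- list(l1 = l1, dr = dr, l2 = l2, dims = d)
  if (collect_trace) trace$logits <- l2$out
  list(logits = l2$out, caches = caches, bn_run = bn_run, trace = trace)
}

# full backward pass; returns gradients in the same tree shape as params
damgcn_bwd <- function(model, caches, dlogits) {
  cfg <- model$config
  p <- model$params
  d <- caches$cls$dims
  b_ <- d[1L]; c_ <- cfg$num_channels; f_ <- cfg$num_bands
  e_ <- cfg$embedding
  g <- list()

  bl2 <- lin_bwd(caches$cls$l2, p$cls_w2, dlogits)
  g$cls_w2 <- bl2$dw; g$cls_b2 <- bl2$db
  dact <- drop_bwd(caches$cls$dr, bl2$dx)
  dh <- dact * gelu_grad(caches$cls$l1$out)
  bl1 <- lin_bwd(caches$cls$l1, p$cls_w1, dh)
  g$cls_w1 <- bl1$dw; g$cls_b1 <- bl1$db
  dz <- bl1$dx

  if (cfg$use_dam) {
    dtf <- matrix(array(dz, c(b_, f_, e_)), b_ * f_, e_)
    g$band_enc <- vector("list", cfg$encoders)
    for (i in rev(seq_len(cfg$encoders))) {
      eb <- enc_bwd(caches$band_enc[[i]], p$band_enc[[i]], dtf)
      g$band_enc[[i]] <- unname_enc_grads(eb$grads)
      dtf <- eb$dx
    }
    gate <- caches$gate
    dpre <- dtf * rep(gate$p, each = b_)
    q <- rowSums(dtf * gate$pre)
    dim(q) <- c(b_, f_)
    dp <- colSums(q)
    g$band_gate <- gate$p * (dp - sum(dp * gate$p))
    blnb <- ln_bwd(caches$band_embed$ln, dpre)
    g$band_embed_lng <- blnb$dg; g$band_embed_lnb <- blnb$db
    dbtok <- blnb$dx
    if (cfg$positional) {
      gp <- rowsum(dbtok, rep(seq_len(f_), each = b_))
      g$band_pos <- gp
    }
    bbe <- lin_bwd(caches$band_embed$lin, p$band_embed_w, dbtok)
    g$band_embed_w <- bbe$dw; g$band_embed_b <- bbe$db
    dbt <- bbe$dx                                 # (B*F) x C
    du <- flat2(aperm(array(dbt, c(b_, f_, c_)), c(1L, 3L, 2L)))
    bue <- lin_bwd(caches$ch_unembed, p$ch_unembed_w, du)
    g$ch_unembed_w <- bue$dw; g$ch_unembed_b <- bue$db
    dtf <- bue$dx
    g$ch_enc <- vector("list", cfg$encoders)
    for (i in rev(seq_len(cfg$encoders))) {
      eb <- enc_bwd(caches$ch_enc[[i]], p$ch_enc[[i]], dtf)
      g$ch_enc[[i]] <- unname_enc_grads(eb$grads)
      dtf <- eb$dx
    }
    blnc <- ln_bwd(caches$ch_embed$ln, dtf)
    g$ch_embed_lng <- blnc$dg; g$ch_embed_lnb <- blnc$db
    dtok <- blnc$dx
    if (cfg$positional)
      g$ch_pos <- rowsum(dtok, rep(seq_len(c_), each = b_))
    bce <- lin_bwd(caches$ch_embed$lin, p$ch_embed_w, dtok)
    g$ch_embed_w <- bce$dw; g$ch_embed_b <- bce$db
    dhh <- array(bce$dx, c(b_, c_, f_))
  } else {
    dhh <- array(dz, c(b_, c_, f_))
  }

  if (cfg$use_gcn) {
    g$gcn <- vector("list", cfg$gcn_layers)
    for (l in rev(seq_len(cfg$gcn_layers))) {
      gb <- gcn_bwd(caches$gcn[[l]], model$graph$propagation,
                    p$gcn[[l]], dhh)
      g$gcn[[l]] <- gb$dw
      dhh <- gb$dx
    }
    bb <- bn_bwd(caches$bn, dhh)
    g$bn_gamma <- bb$dgamma; g$bn_beta <- bb$dbeta
  }
  # return in the exact order of the parameter tree
  g[names(model$params)]
}

# map enc_bwd's d-prefixed names back onto encoder parameter names
unname_enc_grads <- function(gr) {
  names(gr) <- sub("^d", "", names(gr))
  gr
}

#' Cross-entropy loss and prediction
#'
#' Softmax cross-entropy averaged over the batch; `damgcn_predict` is the
#' argmax class.
#'
#' @param logits batch x classes matrix.
#' @param labels 0-based integer class labels.
#' @return `cross_entropy`: list with `loss`, `grad` (d loss / d logits)
#'   and `probs`; `damgcn_predict`: integer vector of 0-based classes.
#' @export
cross_entropy <- function(logits, labels) {
  labels <- as.integer(labels)
  n <- nrow(logits)
  stopifnot(length(labels) == n)
  if (any(labels < 0L) || any(labels >= ncol(logits)))
    stop("labels must lie in [0, num_classes)", call. = FALSE)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  idx <- cbind(seq_len(n), labels + 1L)
  probs <- exp(logits - lse)
  grad <- probs
  grad[idx] <- grad[idx] - 1
  list(loss = mean(lse - logits[idx]), grad = grad / n, probs = probs)
}

#' @rdname cross_entropy
#' @param model a `damgcn_model`.
#' @param features samples x channels x bands array.
#' @param batch_size evaluation batch size.
#' @export
damgcn_predict <- function(model, features, batch_size = 256L) {
  n <- dim(features)[1L]
  out <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    lg <- damgcn_fwd(model, features[idx, , , drop = FALSE])$logits
    out[idx] <- max.col(lg, ties.method = "first") - 1L
  }
  out
}

#' Band gate proportions of a model
#'
#' Softmax of the learnable band gate: the reported "weight proportion" of
#' each frequency band.  Exactly uniform (`1/F`) at initialization.
#'
#' @param model a `damgcn_model` with `use_dam = TRUE`.
#' @return named numeric vector summing to 1.
#' @export
band_proportions <- function(model) {
  if (is.null(model$params$band_gate))
    stop("model has no band gate (use_dam = FALSE)", call. = FALSE)
  p <- softmax_vec(model$params$band_gate)
  names(p) <- paste0("band", seq_along(p))
  p
}

# ---- functional single-operation wrappers (documented public surface) ----

#' GELU activation
#'
#' The sigmoid approximation `x * sigmoid(1.702 * x)`.
#'
#' @param x numeric vector/array.
#' @export
gelu <- function(x) gelu_raw(x)

#' One residual graph-convolution layer
#'
#' Computes `GELU(P %*% H %*% W + H)` per sample, where `P` is the
#' normalized propagation matrix.
#'
#' @param h batch x channels x features array (a single channels x
#'   features matrix is promoted to batch 1).
#' @param graph an `electrode_graph` (normalized), or a bare propagation
#'   matrix.
#' @param w features_in x features_out weight matrix; the residual
#'   requires `features_out == features_in`.
#' @param residual add the input back before activation (needs square
#'   `w`).
#' @param activation apply the GELU; `FALSE` returns the pre-activation.
#' @param double_activation also apply GELU inside, before the residual.
#' @return array of the same batch/channel shape.
#' @export
gcn_layer <- function(h, graph, w, residual = TRUE, activation = TRUE,
                      double_activation = FALSE) {
  prop <- if (inherits(graph, "electrode_graph")) graph$propagation
  else graph
  if (is.null(prop)) stop("graph has no propagation matrix", call. = FALSE)
  single <- is.matrix(h)
  if (single) h <- array(h, c(1L, dim(h)))
  z <- feat_mul(graph_mul(prop, h), w)
  if (double_activation) z <- gelu_raw(z)
  s <- if (residual) z + h else z
  out <- if (activation) gelu_raw(s) else s
  if (single) out <- array(out, dim(out)[2:3])
  out
}

#' Batch normalization (per-channel)
#'
#' Normalizes each channel over the (batch, band) axes:
#' `gamma * (x - mu) / sqrt(sigma^2 + eps) + beta`.  In training mode the
#' batch statistics are used (batch must be >= 2) and running statistics
#' are updated; in eval mode the supplied running statistics apply.
#'
#' @param x batch x channels x bands array.
#' @param gamma,beta scale/shift, length channels (default 1/0).
#' @param training logical.
#' @param running optional list(mean, var, seen) of running statistics.
#' @return list with `output` (same shape) and updated `running`.
#' @export
batch_norm <- function(x, gamma = NULL, beta = NULL, training = TRUE,
                       running = NULL) {
  c_ <- dim(x)[2L]
  gamma <- gamma %||% rep(1, c_)
  beta <- beta %||% numeric(c_)
  running <- running %||% list(mean = numeric(c_), var = rep(1, c_),
                               seen = FALSE)
  r <- bn_fwd(x, gamma, beta, running, training)
  list(output = r$out, running = r$run)
}

#' Multi-head self-attention over a token stack
#'
#' Scaled dot-product attention per head, heads concatenated, output
#' projection.  Returns the row-stochastic attention matrices alongside
#' the output.
#'
#' @param tokens batch x T x E array.
#' @param params list with `wq, bq, wk, bk, wv, bv, wo, bo` (weights
#'   E x heads*dk, output projection heads*dk x E).
#' @param heads number of heads; `dk` defaults to `ncol(wq) / heads`.
#' @param dropout attention dropout (training mode only).
#' @param training logical.
#' @return list: `output` (batch x T x E), `attention` (T x T x heads x
#'   batch, rows sum to 1), `attention_mean` (heads x T x T, batch mean).
#' @export
multi_head_attention <- function(tokens, params, heads, dropout = 0,
                                 training = FALSE) {
  d <- dim(tokens)
  dk <- ncol(params$wq) %/% heads
  r <- mha_fwd(flat2(tokens), d[1L], d[2L], params, heads, dk, dropout,
               training)
  a4 <- mha_attention_array(r)
  list(output = unflat2(r$out, d[1L], d[2L]),
       attention = a4,
       attention_mean = enc_attention(list(mha = r)))
}

#' Band gate
#'
#' Scales each band's token by the softmax of a learnable gate vector.
#' A zero gate gives exactly uniform proportions `1/F`.
#'
#' @param tokens batch x F x E array.
#' @param g gate vector of length F.
#' @return list: `output` (scaled tokens), `proportions` (softmax of `g`).
#' @export
band_gate <- function(tokens, g) {
  d <- dim(tokens)
  stopifnot(length(g) == d[2L])
  p <- softmax_vec(g)
  out <- flat2(tokens) * rep(p, each = d[1L])
  list(output = unflat2(out, d[1L], d[2L]), proportions = p)
}

#' Forward pass with attention trace
#'
#' Runs the network in eval mode and records the quantities the
#' interpretability module consumes.
#'
#' @param model a `damgcn_model`.
#' @param features batch x channels x bands array.
#' @return list: `logits`, `channel_attention` / `band_attention` (one
#'   heads x T x T batch-mean matrix per encoder), `band_proportions`.
#' @export
damgcn_trace <- function(model, features) {
  r <- damgcn_fwd(model, features, training = FALSE, collect_trace = TRUE)
  r$trace
}
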
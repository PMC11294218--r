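test_that("gelu matches its sigmoid approximation pointwise", {
  expect_identical(gelu(0), 0)
  expect_equal(gelu(10), 10, tolerance = 1e-6)
  expect_equal(gelu(1), 1 / (1 + exp(-1.702)), tolerance = 1e-12)
  expect_equal(gelu(-1), -1 / (1 + exp(1.702)), tolerance = 1e-12)
})

test_that("batch norm matches a hand-rolled per-channel oracle", {
  set.seed(4)
  x <- array(rnorm(16 * 5 * 3, mean = 2, sd = 3), c(16, 5, 3))
  gamma <- runif(5, 0.5, 2)
  beta <- rnorm(5)
  out <- batch_norm(x, gamma, beta, training = TRUE)$output
  # oracle: plain loops over channels
  expected <- x
  for (c_ in 1:5) {
    v <- x[, c_, ]
    mu <- mean(v)
    s2 <- mean((v - mu)^2)
    expected[, c_, ] <- gamma[c_] * (v - mu) / sqrt(s2 + 1e-5) + beta[c_]
  }
  expect_equal(out, expected, tolerance = 1e-6)

  # normalized input passes through at gamma = 1, beta = 0
  xn <- array(rnorm(200 * 2 * 2), c(200, 2, 2))
  for (c_ in 1:2) xn[, c_, ] <- (xn[, c_, ] - mean(xn[, c_, ])) /
      sd(as.vector(xn[, c_, ]))
  expect_equal(batch_norm(xn, training = TRUE)$output, xn,
               tolerance = 1e-2)

  # constant input lands on beta through the epsilon path
  xc <- array(5, c(8, 3, 2))
  expect_equal(batch_norm(xc, beta = c(1, 2, 3),
                          training = TRUE)$output[1, , 1],
               c(1, 2, 3), tolerance = 1e-6)

  expect_error(batch_norm(array(1, c(1, 2, 2)), training = TRUE),
               "batch >= 2")
})

test_that("graph convolution matches a dense brute-force oracle", {
  # identity propagation, identity weights, pre-activation, no residual
  h <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  expect_equal(gcn_layer(h, diag(3), diag(4), residual = FALSE,
                         activation = FALSE), h)

  # 3-node toy graph against an explicit triple loop
  g <- electrode_graph(random_montage(3, seed = 6))
  w <- matrix(rnorm(16), 4)
  out <- gcn_layer(h, g, w, residual = TRUE, activation = TRUE)
  p <- g$propagation
  expected <- h
  for (b in 1:2) {
    s <- p %*% h[b, , ] %*% w + h[b, , ]
    expected[b, , ] <- s / (1 + exp(-1.702 * s))
  }
  expect_equal(out, expected, tolerance = 1e-6)

  # constant node features stay constant under a regular graph's
  # propagation (row sums equal by symmetry)
  eq <- montage(c("a", "b", "c"),
                rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  ge <- electrode_graph(eq)
  hc <- array(rep(c(1, 2), each = 3), c(1, 3, 2))  # same across nodes
  pre <- gcn_layer(hc, ge, diag(2), residual = FALSE,
                   activation = FALSE)
  expect_equal(pre[1, 1, ], pre[1, 2, ], tolerance = 1e-12)
  expect_equal(pre[1, 1, ], pre[1, 3, ], tolerance = 1e-12)
})

test_that("gcn block is channel-permutation equivariant", {
  m <- random_montage(6, seed = 8)
  g <- electrode_graph(m)
  w <- matrix(rnorm(9), 3)
  h <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  out <- gcn_layer(h, g, w)
  perm <- c(4, 1, 6, 3, 2, 5)
  gp <- electrode_graph(montage(m$channels[perm], m$coords[perm, ]))
  outp <- gcn_layer(h[, perm, , drop = FALSE], gp, w)
  expect_equal(outp, out[, perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("attention rows are stochastic and match a by-hand oracle", {
  e <- 4; t_ <- 2
  set.seed(2)
  x <- array(rnorm(1 * t_ * e), c(1, t_, e))
  params <- list(wq = matrix(rnorm(e * e), e), bq = numeric(e),
                 wk = matrix(rnorm(e * e), e), bk = numeric(e),
                 wv = matrix(rnorm(e * e), e), bv = numeric(e),
                 wo = diag(e), bo = numeric(e))
  r <- multi_head_attention(x, params, heads = 1)
  # scalar hand computation, one head, T = 2
  xm <- x[1, , ]
  q <- xm %*% params$wq; k <- xm %*% params$wk; v <- xm %*% params$wv
  s <- q %*% t(k) / sqrt(e)
  a_hand <- t(apply(s, 1, function(r_) exp(r_ - max(r_)) /
                      sum(exp(r_ - max(r_)))))
  expect_equal(r$attention[, , 1, 1], a_hand, tolerance = 1e-8)
  expect_equal(r$output[1, , ], a_hand %*% v, tolerance = 1e-8)

  # zero queries/keys give exactly uniform rows
  params0 <- params
  params0$wq[] <- 0; params0$wk[] <- 0
  r0 <- multi_head_attention(x, params0, heads = 2)
  expect_equal(r0$attention[, , 1, 1], matrix(1 / t_, t_, t_))

  # any input: rows sum to 1
  xb <- array(rnorm(3 * 5 * 8), c(3, 5, 8))
  pb <- list(wq = matrix(rnorm(8 * 8), 8), bq = rnorm(8),
             wk = matrix(rnorm(8 * 8), 8), bk = rnorm(8),
             wv = matrix(rnorm(8 * 8), 8), bv = rnorm(8),
             wo = matrix(rnorm(8 * 8), 8), bo = rnorm(8))
  rb <- multi_head_attention(xb, pb, heads = 4)
  sums <- apply(rb$attention, c(1, 3, 4), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-6)
})

test_that("band gate is an exact softmax with uniform zero-init", {
  tok <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  r <- band_gate(tok, numeric(5))
  expect_identical(unname(r$proportions), rep(0.2, 5))
  expect_equal(r$output, tok * 0.2)

  r2 <- band_gate(array(1, c(1, 5, 2)), c(log(2), 0, 0, 0, 0))
  expect_equal(unname(r2$proportions), c(1 / 3, rep(1 / 6, 4)),
               tolerance = 1e-12)

  set.seed(9)
  r3 <- band_gate(tok, rnorm(5))
  expect_equal(sum(r3$proportions), 1, tolerance = 1e-12)

  # a fresh model reports the same uniform proportions
  model <- damgcn_model(damgcn_config(8, 5, 2, embedding = 16,
                                      encoders = 1, heads = 2,
                                      use_gcn = FALSE))
  expect_identical(unname(band_proportions(model)), rep(0.2, 5))
})

test_that("forward pass honours shapes, ablations and determinism", {
  g <- tiny_graph()
  x <- array(rnorm(6 * 8 * 4), c(6, 8, 4))

  set.seed(1)
  model <- damgcn_model(tiny_config(), g)
  fw <- damgcn_fwd(model, x)
  expect_equal(dim(fw$logits), c(6, 2))

  # linear-only variant has no gcn/attention parameters at all
  set.seed(1)
  lin <- damgcn_model(tiny_config(use_gcn = FALSE, use_dam = FALSE))
  expect_named(lin$params, c("cls_w1", "cls_b1", "cls_w2", "cls_b2"))
  expect_equal(nrow(lin$params$cls_w1), 8 * 4)
  expect_equal(dim(damgcn_fwd(lin, x)$logits), c(6, 2))

  # gcn-only and dam-only variants run too
  set.seed(1)
  expect_equal(dim(damgcn_fwd(damgcn_model(tiny_config(use_dam = FALSE),
                                           g), x)$logits), c(6, 2))
  set.seed(1)
  expect_equal(dim(damgcn_fwd(damgcn_model(tiny_config(use_gcn = FALSE)),
                              x)$logits), c(6, 2))

  # bit-identical logits for identical seeds, including dropout path
  run <- function() {
    set.seed(33)
    m <- damgcn_model(tiny_config(), g)
    set.seed(34)
    damgcn_fwd(m, x, training = TRUE)$logits
  }
  expect_identical(run(), run())

  # mismatched input shape is rejected
  expect_error(damgcn_fwd(model, array(0, c(2, 7, 4))))
})

test_that("cross entropy matches a scalar oracle and flags bad labels", {
  # uniform logits: loss is log(K)
  expect_equal(cross_entropy(matrix(0, 4, 3), c(0, 1, 2, 0))$loss,
               log(3), tolerance = 1e-12)
  # argmax prediction
  expect_equal(which.max(c(10, 0, 0)) - 1L, 0L)
  set.seed(5)
  lg <- matrix(rnorm(6 * 4), 6)
  y <- sample(0:3, 6, replace = TRUE)
  ce <- cross_entropy(lg, y)
  # scalar softmax + log-sum oracle
  oracle <- mean(vapply(1:6, function(i) {
    p <- exp(lg[i, ]) / sum(exp(lg[i, ]))
    -log(p[y[i] + 1])
  }, 0))
  expect_equal(ce$loss, oracle, tolerance = 1e-6)
  # gradient rows sum to 0 (softmax minus one-hot)
  expect_equal(rowSums(ce$grad), rep(0, 6), tolerance = 1e-12)
  expect_error(cross_entropy(lg, c(0, 1, 2, 4, 0, 0)),
               "\\[0, num_classes\\)")
})

test_that("autodiff matches finite differences on a sampled subset", {
  set.seed(42)
  graph <- electrode_graph(random_montage(4, seed = 1))
  model <- damgcn_model(grad_config(positional = TRUE), graph)
  x <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  y <- sample(0:1, 5, replace = TRUE)
  loss_at <- function(params) {
    m <- model
    m$params <- params
    cross_entropy(damgcn_fwd(m, x, training = TRUE)$logits, y)$loss
  }
  fw <- damgcn_fwd(model, x, training = TRUE)
  grads <- damgcn_bwd(model, fw$caches,
                      cross_entropy(fw$logits, y)$grad)
  paths <- param_leaf_paths(model$params)
  set.seed(7)
  picked <- paths[sample(seq_along(paths), 20)]
  h <- 1e-5
  for (pth in picked) {
    leaf <- tree_get(model$params, pth)
    j <- sample(seq_along(leaf), 1)
    up <- leaf; up[j] <- leaf[j] + h
    dn <- leaf; dn[j] <- leaf[j] - h
    fd <- (loss_at(tree_set(model$params, pth, up)) -
             loss_at(tree_set(model$params, pth, dn))) / (2 * h)
    an <- tree_get(grads, pth)[j]
    expect_lt(abs(fd - an) / max(1e-4, abs(fd) + abs(an)), 1e-4)
  }
})

test_that("per-head dimension floors when embedding is not divisible", {
  cfg <- damgcn_config(8, 4, 2, embedding = 64, heads = 6,
                       use_gcn = FALSE)
  expect_equal(cfg$dk, 10)
  expect_equal(cfg$hd, 60)
  m <- damgcn_model(cfg)
  expect_equal(ncol(m$params$ch_enc[[1]]$wq), 60)
  expect_equal(dim(m$params$ch_enc[[1]]$wo), c(60, 64))
  # a graph is mandatory as soon as the gcn block is on
  expect_error(damgcn_model(damgcn_config(8, 4, 2)), "requires a graph")
})

test_that("model checkpoints round-trip through JSON", {
  set.seed(12)
  g <- tiny_graph()
  model <- damgcn_model(tiny_config(), g)
  x <- array(rnorm(4 * 8 * 4), c(4, 8, 4))
  f <- tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_equal(damgcn_fwd(back, x)$logits, damgcn_fwd(model, x)$logits,
               tolerance = 1e-10)
  suppressWarnings(expect_error(load_model(tempfile())))
})
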
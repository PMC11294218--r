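#' Training configuration
#'
#' Defaults follow the published setting: at most 200 epochs, batch size
#' 64, Adam with learning rate 0.001 (other Adam constants at their
#' conventional defaults, no weight decay), dropout carried by the model
#' config.  Early stopping watches validation accuracy on a held-out
#' fraction of the *training* split (never the test fold) with a patience
#' of 30 epochs and restores the best weights.
#'
#' @param max_epochs cap on training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param patience early-stopping patience in epochs.
#' @param val_fraction fraction of the training split held out for early
#'   stopping (stratified).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(max_epochs = 200L, batch_size = 64L,
                         learning_rate = 1e-3, patience = 30L,
                         val_fraction = 0.1, seed = 1L) {
  stopifnot(max_epochs >= 1, batch_size >= 2, learning_rate > 0,
            patience >= 1, val_fraction > 0, val_fraction < 0.5)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# ---- Adam over a nested parameter tree ----

tree_map <- function(a, f) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- tree_map(a[[i]], f)
    a
  } else f(a)
}

tree_map3 <- function(a, b, c_, f) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- tree_map3(a[[i]], b[[i]], c_[[i]], f)
    a
  } else f(a, b, c_)
}

adam_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map3(state$m, grads, grads,
                       function(m, g, .) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map3(state$v, grads, grads,
                       function(v, g, .) beta2 * v + (1 - beta2) * g * g)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map3(params, state$m, state$v, function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  list(params = params, state = state)
}

# stratified index sample of about `frac` of idx (>= 1 per class)
stratified_holdout <- function(idx, labels, frac) {
  take <- unlist(lapply(split(idx, labels[idx]), function(ix) {
    n <- max(1L, round(length(ix) * frac))
    if (length(ix) == 1L) ix else sample(ix, n)
  }), use.names = FALSE)
  sort(take)
}

model_accuracy <- function(model, features, labels) {
  mean(damgcn_predict(model, features) == as.integer(labels))
}

#' Train a model on one split
#'
#' Minibatch Adam on softmax cross-entropy with early stopping on
#' held-out validation accuracy.  Fully deterministic given
#' `config$seed`: initialization, the validation split, shuffling and
#' dropout all flow from it.
#'
#' @param features samples x channels x bands array (DE features).
#' @param labels 0-based integer class labels, one per sample.
#' @param graph an `electrode_graph` (required unless
#'   `model_config$use_gcn` is `FALSE`).
#' @param model_config a [damgcn_config()].
#' @param config a [train_config()].
#' @param train_idx indices to train on (default: all samples).
#' @param verbose print per-epoch progress.
#' @return a `damgcn_fit`: `model` (early-stopped best-validation
#'   weights), `final_model` (converged end-of-training weights, used by
#'   the interpretability readouts), `history` (data.frame epoch /
#'   train_loss / val_accuracy), `band_trajectory` (matrix of per-epoch
#'   band proportions, first row = initialization), `best_epoch`,
#'   `stopped_epoch`.
#' @export
train_damgcn <- function(features, labels, graph = NULL, model_config,
                         config = train_config(), train_idx = NULL,
                         verbose = FALSE) {
  labels <- as.integer(labels)
  n_all <- dim(features)[1L]
  stopifnot(length(labels) == n_all)
  train_idx <- train_idx %||% seq_len(n_all)
  set.seed(config$seed)

  val_idx <- stratified_holdout(train_idx, labels, config$val_fraction)
  fit_idx <- setdiff(train_idx, val_idx)
  stopifnot(length(fit_idx) >= 2L, length(val_idx) >= 1L)
  batch <- min(config$batch_size, length(fit_idx))
  xval <- features[val_idx, , , drop = FALSE]
  yval <- labels[val_idx]

  model <- damgcn_model(model_config, graph)
  opt <- adam_init(model$params)
  has_gate <- !is.null(model$params$band_gate)
  traj <- if (has_gate) list(softmax_vec(model$params$band_gate))

  best <- list(acc = -Inf, params = model$params, bn_run = model$bn_run,
               epoch = 0L)
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_accuracy = numeric())

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(fit_idx)
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = batch)) {
      bi <- ord[start:min(start + batch - 1L, length(ord))]
      if (length(bi) < 2L) next  # batch norm needs >= 2 in training
      fw <- damgcn_fwd(model, features[bi, , , drop = FALSE],
                       training = TRUE)
      model$bn_run <- fw$bn_run
      ce <- cross_entropy(fw$logits, labels[bi])
      if (!is.finite(ce$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      grads <- damgcn_bwd(model, fw$caches, ce$grad)
      st <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- st$params
      opt <- st$state
      losses <- c(losses, ce$loss)
    }
    acc <- model_accuracy(model, xval, yval)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_accuracy = acc))
    if (has_gate) traj[[epoch + 1L]] <- softmax_vec(model$params$band_gate)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f", epoch,
                      mean(losses), acc))
    if (acc > best$acc + 1e-12) {
      best <- list(acc = acc, params = model$params,
                   bn_run = model$bn_run, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  # the returned model carries the early-stopped (best-validation)
  # weights; the converged end-of-training weights are kept alongside
  # because interpretability reads parameters at convergence
  final_model <- model
  model$params <- best$params
  model$bn_run <- best$bn_run
  structure(list(model = model, final_model = final_model,
                 history = hist,
                 band_trajectory = if (has_gate)
                   do.call(rbind, traj),
                 best_epoch = best$epoch, stopped_epoch = nrow(hist),
                 val_accuracy = best$acc),
            class = "damgcn_fit")
}

#' @export
print.damgcn_fit <- function(x, ...) {
  cat("<damgcn_fit> stopped at epoch ", x$stopped_epoch,
      " (best epoch ", x$best_epoch, "), val accuracy ",
      sprintf("%.3f", x$val_accuracy), "\n", sep = "")
  invisible(x)
}
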
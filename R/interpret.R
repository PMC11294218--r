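#' Per-band weight proportions over training
#'
#' Reads the softmax-normalized band gate out of a training run: one row
#' per epoch (row 1 = initialization, exactly uniform `1/F`).
#'
#' @param fit a `damgcn_fit` from [train_damgcn()], or a list of models /
#'   gate vectors ordered by epoch.
#' @param band_names optional column names.
#' @return matrix (epochs + 1) x F, rows summing to 1.
#' @export
band_weight_trajectory <- function(fit, band_names = NULL) {
  traj <- if (inherits(fit, "damgcn_fit")) {
    if (is.null(fit$band_trajectory))
      stop("fit has no band gate (use_dam = FALSE)", call. = FALSE)
    fit$band_trajectory
  } else {
    do.call(rbind, lapply(fit, function(ck) {
      g <- if (inherits(ck, "damgcn_model")) ck$params$band_gate else ck
      if (is.null(g)) stop("checkpoint has no band gate", call. = FALSE)
      softmax_vec(g)
    }))
  }
  if (!is.null(band_names)) colnames(traj) <- band_names
  traj
}

#' Degree centrality of an attention (or adjacency) matrix
#'
#' `DC_i = k_i / (N - 1)` with `k_i` the summed connection weight of node
#' i.  Attention matrices are asymmetric, so by default the matrix is
#' symmetrized (`(A + t(A)) / 2`) and the self-weight excluded, which
#' makes the complete unit-weight graph score exactly 1 (the classical
#' definition); `mode = "in"` / `"out"` use raw column/row strengths
#' instead.
#'
#' @param attention nonnegative square matrix.
#' @param mode `"symmetric"` (default), `"in"` or `"out"`.
#' @return numeric vector of length N.
#' @export
degree_centrality <- function(attention,
                              mode = c("symmetric", "in", "out")) {
  mode <- match.arg(mode)
  if (!is.matrix(attention) || nrow(attention) != ncol(attention))
    stop("attention must be a square matrix", call. = FALSE)
  n <- nrow(attention)
  a <- switch(mode,
              symmetric = (attention + t(attention)) / 2,
              "in" = t(attention),
              out = attention)
  diag(a) <- 0
  k <- rowSums(a)
  k / (n - 1)
}

#' Channel importance from the trained channel-attention matrices
#'
#' Runs the model over evaluation samples, averages the channel-encoder
#' attention matrices over heads, encoder layers and samples, and scores
#' each electrode by degree centrality of the averaged matrix.
#'
#' @param model a trained `damgcn_model` with `use_dam = TRUE`.
#' @param features samples x channels x bands array.
#' @param batch_size evaluation batch size.
#' @param layers which channel encoders to average (default all).
#' @param mode forwarded to [degree_centrality()].
#' @return an `attention_report`: `channel_centrality` (named length-C
#'   vector), `mean_attention` (C x C), `band_proportions`,
#'   `channel_names`, `aggregation` metadata.
#' @export
channel_importance <- function(model, features, batch_size = 256L,
                               layers = NULL, mode = "symmetric") {
  if (!model$config$use_dam)
    stop("model has no attention block (use_dam = FALSE)", call. = FALSE)
  n <- dim(features)[1L]
  c_ <- model$config$num_channels
  layers <- layers %||% seq_len(model$config$encoders)
  acc <- matrix(0, c_, c_)
  nb <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    tr <- damgcn_trace(model, features[idx, , , drop = FALSE])
    for (l in layers) {
      a <- tr$channel_attention[[l]]       # heads x C x C, batch mean
      acc <- acc + apply(a, c(2L, 3L), mean) * length(idx)
    }
    nb <- nb + length(idx)
  }
  mean_att <- acc / (nb * length(layers))
  names_ <- model$graph$channel_names %||% paste0("ch", seq_len(c_))
  dc <- degree_centrality(mean_att, mode = mode)
  names(dc) <- names_
  structure(list(channel_centrality = dc, mean_attention = mean_att,
                 band_proportions = band_proportions(model),
                 channel_names = names_,
                 aggregation = list(samples = n, layers = layers,
                                    heads = model$config$heads,
                                    mode = mode)),
            class = "attention_report")
}

#' @export
print.attention_report <- function(x, ...) {
  top <- sort(x$channel_centrality, decreasing = TRUE)
  cat("<attention_report> ", length(x$channel_centrality),
      " channels; top: ",
      paste(sprintf("%s (%.3f)", names(head(top, 5L)), head(top, 5L)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Band weights read from the band-encoder attention (alternative
#' extractor)
#'
#' Instead of the explicit gate, scores each band by the mean attention
#' mass its token receives in the band encoders, normalized to sum to 1.
#' Provided for comparison with [band_proportions()].
#'
#' @inheritParams channel_importance
#' @return numeric vector of length F summing to 1.
#' @export
band_attention_weights <- function(model, features, batch_size = 256L) {
  if (!model$config$use_dam)
    stop("model has no attention block (use_dam = FALSE)", call. = FALSE)
  n <- dim(features)[1L]
  f_ <- model$config$num_bands
  acc <- numeric(f_)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    tr <- damgcn_trace(model, features[idx, , , drop = FALSE])
    for (a in tr$band_attention)
      acc <- acc + colMeans(apply(a, c(2L, 3L), mean)) * length(idx)
  }
  acc / sum(acc)
}

#' Export channel importances for topographic mapping
#'
#' Writes a per-channel CSV (`name, x, y, z, value`) joining the report
#' to montage positions; [plot_topomap()] renders a simple 2-D scalp
#' projection from the same data.
#'
#' @param report an `attention_report` (or named numeric vector).
#' @param mont the matching [montage()].
#' @param path output CSV path.
#' @export
topomap_export <- function(report, mont, path) {
  vals <- if (inherits(report, "attention_report"))
    report$channel_centrality else report
  if (!setequal(names(vals), mont$channels)) {
    off <- c(setdiff(names(vals), mont$channels),
             setdiff(mont$channels, names(vals)))
    stop("channel names do not match montage: ",
         paste(unique(off), collapse = ", "), call. = FALSE)
  }
  vals <- vals[mont$channels]
  df <- data.frame(name = mont$channels, mont$coords,
                   value = as.numeric(vals))
  data.table::fwrite(df, path)
  invisible(df)
}

#' @rdname topomap_export
#' @param main plot title.
#' @param ... passed to [graphics::symbols()].
#' @export
plot_topomap <- function(report, mont, main = "channel importance", ...) {
  vals <- if (inherits(report, "attention_report"))
    report$channel_centrality else report
  vals <- vals[mont$channels]
  # azimuthal projection: angle from vertex becomes the radius
  xyz <- mont$coords
  r <- acos(pmin(1, pmax(-1, xyz[, "z"])))
  az <- atan2(xyz[, "x"], xyz[, "y"])
  px <- r * sin(az)
  py <- r * cos(az)
  rel <- (vals - min(vals)) / max(1e-12, diff(range(vals)))
  graphics::plot(px, py, asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = main, type = "n")
  graphics::symbols(px, py, circles = 0.03 + 0.12 * rel, inches = FALSE,
                    add = TRUE, bg = grDevices::grey(1 - 0.8 * rel), ...)
  graphics::text(px, py, mont$channels, cex = 0.5, pos = 3)
  invisible(data.frame(x = px, y = py, value = as.numeric(vals)))
}
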
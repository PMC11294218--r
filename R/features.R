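#' Differential-entropy feature tensor
#'
#' Turns a raw recording into the model input: per trial, drop the
#' baseline, band-limit the whole trial (so segment edges never truncate
#' the filter), cut non-overlapping segments, and compute the differential
#' entropy of every (segment, channel, band) cell.
#'
#' With `method = "filter"` (default) each band is realized as an exact
#' zero-phase FFT-mask band-pass of the trial and DE is taken from the
#' time-domain variance of each segment.  With `method = "stft"` the
#' variance is estimated per segment from a Hann-windowed spectrum binned
#' into bands; both estimators agree in expectation for stationary
#' signals.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [band_spec()]; defaults to the five canonical bands.
#' @param segment_seconds non-overlapping window length (seconds).
#' @param method `"filter"` or `"stft"`.
#' @param var_floor variance clamp passed to [de_from_variance()].
#' @return a `de_features` object: `features` (samples x channels x bands
#'   array of DE in nats), `sample_index` (data.frame trial / segment /
#'   subject), `labels` (per-sample, from per-trial labels, or `NULL`),
#'   `band_names`, `channel_names`, `segment_seconds`.
#' @export
extract_features <- function(rec, spec = eeg_bands(), segment_seconds = 1,
                             method = c("filter", "stft"),
                             var_floor = 1e-12) {
  stopifnot(inherits(rec, "eeg_recording"))
  method <- match.arg(method)
  spec <- clip_bands(spec, rec$fs)
  nb <- nrow(spec)
  nch <- nrow(rec$signal[[1L]])
  seglen <- as.integer(round(segment_seconds * rec$fs))

  per_trial <- vector("list", length(rec$signal))
  for (tr in seq_along(rec$signal)) {
    trial <- rec$signal[[tr]]
    drop <- as.integer(round(rec$baseline_seconds * rec$fs))
    usable <- trial[, (drop + 1L):ncol(trial), drop = FALSE]
    nseg <- ncol(usable) %/% seglen
    if (nseg < 1L) {
      warning("trial ", tr, " shorter than one segment; skipped",
              call. = FALSE)
      per_trial[[tr]] <- array(0, c(0L, nch, nb))
      next
    }
    de <- array(0, c(nseg, nch, nb))
    if (method == "filter") {
      xt <- t(usable)  # time x channels
      for (b in seq_len(nb)) {
        xb <- fft_bandpass(xt, rec$fs, spec$low[b], spec$high[b])
        for (s in seq_len(nseg)) {
          seg <- xb[((s - 1L) * seglen + 1L):(s * seglen), , drop = FALSE]
          seg <- sweep(seg, 2L, colMeans(seg))
          de[s, , b] <- de_from_variance(colSums(seg^2) / seglen, var_floor)
        }
      }
    } else {
      for (s in seq_len(nseg)) {
        seg <- usable[, ((s - 1L) * seglen + 1L):(s * seglen),
                      drop = FALSE]
        de[s, , ] <- de_from_variance(
          stft_band_variance(seg, rec$fs, spec), var_floor)
      }
    }
    per_trial[[tr]] <- de
  }

  nsegs <- vapply(per_trial, function(a) dim(a)[1L], 1L)
  total <- sum(nsegs)
  features <- array(0, c(total, nch, nb),
                    dimnames = list(NULL, rec$channel_names, spec$name))
  at <- 0L
  for (tr in seq_along(per_trial)) {
    if (nsegs[tr] > 0L)
      features[(at + 1L):(at + nsegs[tr]), , ] <- per_trial[[tr]]
    at <- at + nsegs[tr]
  }
  sample_index <- data.frame(
    trial = rep(seq_along(per_trial), nsegs),
    segment = unlist(lapply(nsegs, seq_len), use.names = FALSE))
  if (!is.null(rec$subject)) sample_index$subject <- rec$subject
  labels <- if (!is.null(rec$labels))
    rep(as.integer(rec$labels), nsegs) else NULL

  structure(list(features = features, sample_index = sample_index,
                 labels = labels, band_names = spec$name,
                 channel_names = rec$channel_names,
                 segment_seconds = segment_seconds),
            class = "de_features")
}

#' @export
print.de_features <- function(x, ...) {
  d <- dim(x$features)
  cat("<de_features> ", d[1L], " samples x ", d[2L], " channels x ",
      d[3L], " bands (", paste(x$band_names, collapse = ", "),
      "), segments of ", x$segment_seconds, " s\n", sep = "")
  invisible(x)
}

#' Combine per-subject feature tensors
#'
#' Stacks samples of several `de_features` objects (same channels/bands)
#' and records each sample's subject for leave-one-subject-out splitting.
#'
#' @param feature_list list of `de_features`.
#' @param subjects identifiers, one per list element; defaults to list
#'   names or positions.
#' @return a single `de_features` with a `subject` column in
#'   `sample_index`.
#' @export
bind_features <- function(feature_list, subjects = NULL) {
  stopifnot(length(feature_list) >= 1L)
  if (is.null(subjects))
    subjects <- names(feature_list) %||% seq_along(feature_list)
  d <- lapply(feature_list, function(f) dim(f$features)[-1L])
  if (length(unique(d)) != 1L)
    stop("feature tensors have mismatched channel/band dimensions",
         call. = FALSE)
  n <- vapply(feature_list, function(f) dim(f$features)[1L], 1L)
  out <- feature_list[[1L]]
  features <- array(0, c(sum(n), d[[1L]]),
                    dimnames = dimnames(out$features))
  at <- 0L
  idx <- vector("list", length(feature_list))
  for (i in seq_along(feature_list)) {
    features[(at + 1L):(at + n[i]), , ] <- feature_list[[i]]$features
    si <- feature_list[[i]]$sample_index[, c("trial", "segment")]
    si$subject <- subjects[[i]]
    idx[[i]] <- si
    at <- at + n[i]
  }
  out$features <- features
  out$sample_index <- do.call(rbind, idx)
  out$labels <- unlist(lapply(feature_list, `[[`, "labels"),
                       use.names = FALSE)
  out
}
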
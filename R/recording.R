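#' EEG recording container
#'
#' Holds one subject's (or session's) raw multichannel EEG: a list of
#' channels x time matrices, one per trial (trials may differ in length),
#' the sampling rate, per-trial labels, and the number of leading baseline
#' seconds to drop before feature extraction.
#'
#' @param signal either a trials x channels x time array or a list of
#'   channels x time matrices.
#' @param fs sampling rate in Hz (> 0).
#' @param labels integer/factor per-trial class labels (0-based integers are
#'   used throughout the package), or `NULL` when only ratings exist.
#' @param baseline_seconds leading seconds of every trial that are
#'   pre-stimulus baseline; dropped during segmentation.
#' @param channel_names optional channel labels.
#' @param ratings optional data.frame of continuous per-trial ratings
#'   (e.g. valence/arousal/dominance on 1-9) to be binarized later.
#' @param subject optional subject identifier.
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(signal, fs, labels = NULL, baseline_seconds = 0,
                          channel_names = NULL, ratings = NULL,
                          subject = NULL) {
  if (is.array(signal) && length(dim(signal)) == 3L) {
    signal <- lapply(seq_len(dim(signal)[1L]),
                     function(i) matrix(signal[i, , ], dim(signal)[2L]))
  }
  stopifnot(is.list(signal), length(signal) >= 1L, fs > 0)
  nch <- unique(vapply(signal, nrow, 1L))
  if (length(nch) != 1L)
    stop("all trials must have the same channel count", call. = FALSE)
  if (!all(vapply(signal, function(m) all(is.finite(m)), TRUE)))
    stop("signal must be finite", call. = FALSE)
  if (!is.null(labels) && length(labels) != length(signal))
    stop("labels length (", length(labels), ") != number of trials (",
         length(signal), ")", call. = FALSE)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  structure(list(signal = signal, fs = fs, labels = labels,
                 baseline_seconds = baseline_seconds,
                 channel_names = as.character(channel_names),
                 ratings = ratings, subject = subject),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  len <- vapply(x$signal, ncol, 1L)
  cat("<eeg_recording> ", length(x$signal), " trials x ",
      nrow(x$signal[[1L]]), " channels @ ", x$fs, " Hz, ",
      if (length(unique(len)) == 1L) paste0(len[1L] / x$fs, " s each")
      else paste0(min(len) / x$fs, "-", max(len) / x$fs, " s"),
      ", baseline ", x$baseline_seconds, " s\n", sep = "")
  invisible(x)
}

#' Cut one trial into non-overlapping segments
#'
#' Drops the leading baseline, then cuts contiguous windows of
#' `segment_seconds`; a trailing partial window is discarded.
#'
#' @param trial channels x time matrix.
#' @param fs sampling rate in Hz.
#' @param segment_seconds window length in seconds; `segment_seconds * fs`
#'   must be a positive integer.
#' @param baseline_seconds leading seconds to drop first.
#' @return list of channels x (segment_seconds * fs) matrices (possibly
#'   empty, with a warning, when the usable duration is shorter than one
#'   window).
#' @export
segment_trial <- function(trial, fs, segment_seconds,
                          baseline_seconds = 0) {
  stopifnot(is.matrix(trial), fs > 0, segment_seconds > 0)
  len <- segment_seconds * fs
  if (abs(len - round(len)) > 1e-9)
    stop("segment_seconds * fs must be an integer number of samples",
         call. = FALSE)
  len <- as.integer(round(len))
  drop <- as.integer(round(baseline_seconds * fs))
  usable <- ncol(trial) - drop
  nseg <- usable %/% len
  if (nseg < 1L) {
    warning("trial shorter than one segment after baseline removal; ",
            "no segments produced", call. = FALSE)
    return(list())
  }
  lapply(seq_len(nseg), function(s) {
    trial[, (drop + (s - 1L) * len + 1L):(drop + s * len), drop = FALSE]
  })
}

#' Differential entropy of a band-limited segment
#'
#' Under the Gaussian assumption the differential entropy of a signal is
#' `0.5 * log(2 * pi * e * sigma^2)` nats, with `sigma^2` the
#' maximum-likelihood (divide by n) variance of the segment.  Zero variance
#' is floored at `var_floor` so the value is always finite.
#'
#' @param x numeric vector (length >= 2).
#' @param var_floor lower clamp for the variance estimate, in signal
#'   units squared.
#' @return differential entropy in nats.
#' @examples
#' differential_entropy(rnorm(1e4))  # ~ 0.5 * log(2 * pi * exp(1))
#' @export
differential_entropy <- function(x, var_floor = 1e-12) {
  stopifnot(length(x) >= 2L)
  de_from_variance(sum((x - mean(x))^2) / length(x), var_floor)
}

#' @rdname differential_entropy
#' @param sigma2 variance(s), any shape.
#' @export
de_from_variance <- function(sigma2, var_floor = 1e-12) {
  0.5 * log(2 * pi * exp(1) * pmax(sigma2, var_floor))
}

#' Binarize 1-9 affective ratings at a threshold
#'
#' Ratings strictly above the threshold map to class 1 (high), all others
#' (including a rating exactly at the threshold) to class 0.
#'
#' @param ratings numeric vector, data.frame or matrix of 1-9 ratings; if
#'   two-dimensional, `dimension` selects the column.
#' @param dimension one of `"valence"`, `"arousal"`, `"dominance"` (used
#'   when `ratings` has named columns).
#' @param threshold split point, default 5.
#' @param strict if `TRUE` (default) class 1 requires rating > threshold;
#'   `FALSE` uses >=.
#' @return integer vector of 0/1 labels.
#' @export
binarize_deap_labels <- function(ratings,
                                 dimension = c("valence", "arousal",
                                               "dominance"),
                                 threshold = 5, strict = TRUE) {
  dimension <- match.arg(dimension)
  if (!is.null(dim(ratings))) {
    if (!dimension %in% colnames(ratings))
      stop("ratings have no '", dimension, "' column", call. = FALSE)
    ratings <- ratings[, dimension]
  }
  ratings <- as.numeric(ratings)
  if (any(!is.finite(ratings)) || any(ratings < 1) || any(ratings > 9))
    stop("ratings must lie in [1, 9]", call. = FALSE)
  if (strict) as.integer(ratings > threshold)
  else as.integer(ratings >= threshold)
}
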
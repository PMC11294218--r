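#' Frequency band specification
#'
#' An ordered set of named frequency bands.  Band membership of a DFT bin
#' at frequency f is `low < f <= high`, so adjacent canonical bands
#' partition the spectrum without overlap and DC is never included.
#'
#' @param name character vector of band names.
#' @param low,high numeric vectors of band edges in Hz (`low < high`).
#' @return a `band_spec` data.frame with columns name, low, high.
#' @examples
#' band_spec("alpha", 8, 13)
#' @export
band_spec <- function(name, low, high) {
  stopifnot(length(name) == length(low), length(low) == length(high),
            length(name) >= 1L)
  if (any(!is.finite(low)) || any(!is.finite(high)) || any(low >= high))
    stop("band edges must be finite with low < high", call. = FALSE)
  if (anyDuplicated(name)) stop("band names must be unique", call. = FALSE)
  structure(data.frame(name = as.character(name), low = as.numeric(low),
                       high = as.numeric(high), stringsAsFactors = FALSE),
            class = c("band_spec", "data.frame"))
}

#' Canonical EEG band sets
#'
#' `"seed"` (the default, also `"all5"`): delta 1-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-75 Hz -- five bands for wide-band research
#' recordings; the open-ended gamma band is capped at the 75 Hz release
#' filter edge.  `"deap"`: theta, alpha, beta, gamma with gamma capped at
#' 45 Hz -- four bands, because that dataset is released band-passed to
#' 4-45 Hz and carries no delta content.
#'
#' @param which `"seed"`, `"all5"` or `"deap"`.
#' @return a [band_spec()].
#' @export
eeg_bands <- function(which = c("seed", "all5", "deap")) {
  which <- match.arg(which)
  if (which == "deap")
    band_spec(c("theta", "alpha", "beta", "gamma"),
              c(4, 8, 13, 30), c(8, 13, 30, 45))
  else
    band_spec(c("delta", "theta", "alpha", "beta", "gamma"),
              c(1, 4, 8, 13, 30), c(4, 8, 13, 30, 75))
}

# clip band edges at Nyquist, warning once per offending band
clip_bands <- function(spec, fs) {
  nyq <- fs / 2
  over <- spec$high > nyq
  if (any(over)) {
    warning("band(s) ", paste(spec$name[over], collapse = ", "),
            " exceed Nyquist (", nyq, " Hz); upper edge clipped",
            call. = FALSE)
    spec$high[over] <- nyq
  }
  if (any(spec$low >= spec$high))
    stop("band entirely above Nyquist: ",
         paste(spec$name[spec$low >= spec$high], collapse = ", "),
         call. = FALSE)
  spec
}

# logical DFT-bin mask for one band (two-sided, n-point transform)
band_bin_mask <- function(n, fs, low, high) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # fold to the two-sided frequency
  f > low & f <= high
}

# fraction of white-noise power an ideal mask for this band retains
band_power_fraction <- function(n, fs, low, high) {
  mean(band_bin_mask(n, fs, low, high))
}

#' Zero-phase FFT band-pass
#'
#' Ideal (brick-wall) band-pass: the DFT of each column is masked to the
#' band's bins and inverted.  Exactly zero phase shift, exact band edges.
#'
#' @param x numeric matrix, time x channels (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz.
#' @return filtered matrix (or vector) of the same shape.
#' @export
fft_bandpass <- function(x, fs, low, high) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  keep <- band_bin_mask(nrow(x), fs, low, high)
  xf <- mvfft(x)
  xf[!keep, ] <- 0 + 0i
  out <- Re(mvfft(xf, inverse = TRUE)) / nrow(x)
  if (vec) drop(out) else out
}

#' Decompose a multichannel segment into band-limited time series
#'
#' @param segment numeric matrix, channels x time.
#' @param fs sampling rate in Hz.
#' @param spec a [band_spec()]; bands above Nyquist are clipped with a
#'   warning.
#' @return array channels x bands x time.
#' @export
band_decompose <- function(segment, fs, spec = eeg_bands()) {
  stopifnot(is.matrix(segment), fs > 0)
  spec <- clip_bands(spec, fs)
  nb <- nrow(spec)
  out <- array(0, dim = c(nrow(segment), nb, ncol(segment)),
               dimnames = list(rownames(segment), spec$name, NULL))
  xt <- t(segment)  # time x channels for the column-wise filter
  for (b in seq_len(nb)) {
    out[, b, ] <- t(fft_bandpass(xt, fs, spec$low[b], spec$high[b]))
  }
  out
}

# Hann-window STFT band variance estimate for one segment:
# sigma^2_band = sum_{k in band} |FFT(w x)_k|^2 / (n * sum(w^2)),
# unbiased for white noise (returns the band's share of total variance).
stft_band_variance <- function(segment, fs, spec) {
  n <- ncol(segment)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  wn <- n * sum(w^2)
  xf <- mvfft(t(segment) * w)
  p <- Mod(xf)^2
  out <- matrix(0, nrow(segment), nrow(spec))
  for (b in seq_len(nrow(spec))) {
    keep <- band_bin_mask(n, fs, spec$low[b], spec$high[b])
    out[, b] <- colSums(p[keep, , drop = FALSE]) / wn
  }
  out
}
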
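#' Synthetic EEG specification
#'
#' Describes a generated dataset with band- and channel-localized class
#' structure.  Every channel's signal is a sum over frequency bands of
#' band-limited Gaussian noise (white noise through the same zero-phase
#' band-pass the analyzer uses, so generator and analyzer agree on band
#' definitions by construction).  In *informative* (band, channel) cells
#' the variance is `noise_sigma^2 * effect_size^class`; everywhere else it
#' is `noise_sigma^2`.  Because DE of a Gaussian is
#' `0.5 * log(2 * pi * e * sigma^2)`, the planted class separation in DE
#' space is exactly `0.5 * class * log(effect_size)` nats in informative
#' cells -- an analytically known signal for recovery tests.  Each subject
#' carries a log-normal scalar gain (sdlog `subject_variability`) applied
#' to all channels, which shifts every DE cell by a common constant and
#' makes cross-subject protocols meaningfully harder.  Trials are labeled
#' round-robin over classes.
#'
#' Defaults emulate one subject of the 32-channel 128 Hz layout: 40
#' trials of 63 s with a 3 s leading baseline (baseline carries no class
#' signal), four bands (theta..gamma), class signal in the gamma band of
#' F3, F4, O1 and O2 with a variance ratio of 4.
#'
#' @param n_subjects,n_trials,trial_seconds,baseline_seconds,fs layout.
#' @param montage montage name or [montage()] object.
#' @param bands a [band_spec()].
#' @param classes number of classes (trials labeled round-robin).
#' @param informative_bands,informative_channels names of cells carrying
#'   class signal.
#' @param effect_size per-class variance multiplier (> 0) in informative
#'   cells.
#' @param noise_sigma baseline signal standard deviation (all units
#'   arbitrary, e.g. microvolts).
#' @param subject_variability sdlog of the per-subject log-normal gain.
#' @param seed RNG seed fixing everything.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_subjects = 1L, n_trials = 40L,
                       trial_seconds = 63, baseline_seconds = 3,
                       fs = 128, montage = "deap32",
                       bands = eeg_bands("deap"), classes = 2L,
                       informative_bands = "gamma",
                       informative_channels = c("F3", "F4", "O1", "O2"),
                       effect_size = 4, noise_sigma = 1,
                       subject_variability = 0.4, seed = 1L) {
  mont <- if (inherits(montage, "eeg_montage")) montage
  else load_standard_montage(montage)
  stopifnot(n_subjects >= 1, n_trials >= 1, trial_seconds > 0,
            baseline_seconds >= 0, fs > 0, classes >= 2,
            effect_size > 0, noise_sigma > 0, subject_variability >= 0)
  if (!all(informative_bands %in% bands$name))
    stop("informative_bands not in band spec: ",
         paste(setdiff(informative_bands, bands$name), collapse = ", "),
         call. = FALSE)
  if (!all(informative_channels %in% mont$channels))
    stop("informative_channels not in montage: ",
         paste(setdiff(informative_channels, mont$channels),
               collapse = ", "), call. = FALSE)
  if (any(bands$low >= fs / 2))
    stop("band entirely above Nyquist for fs = ", fs, call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 trial_seconds = trial_seconds,
                 baseline_seconds = baseline_seconds, fs = fs,
                 montage = mont, bands = bands,
                 classes = as.integer(classes),
                 informative_bands = informative_bands,
                 informative_channels = informative_channels,
                 effect_size = effect_size, noise_sigma = noise_sigma,
                 subject_variability = subject_variability,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# band-limited Gaussian noise, channels x n, unit variance in expectation
.band_noise <- function(nch, n, fs, low, high) {
  frac <- band_power_fraction(n, fs, low, high)
  w <- matrix(rnorm(nch * n), n, nch)
  t(fft_bandpass(w, fs, low, high)) / sqrt(frac)
}

#' Generate a synthetic dataset
#'
#' @param spec a [synth_spec()].
#' @return a `synth_dataset`: `recordings` (list of [eeg_recording()],
#'   one per subject, with 0-based labels and 1-9 style ratings for
#'   2-class specs), `spec`, and `ground_truth` (informative cells,
#'   per-class cell variances, subject gains).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  mont <- spec$montage
  nch <- length(mont$channels)
  bands <- clip_bands(spec$bands, spec$fs)
  nbase <- as.integer(round(spec$baseline_seconds * spec$fs))
  nsig <- as.integer(round(spec$trial_seconds * spec$fs)) - nbase
  stopifnot(nsig > 0)
  inf_ch <- mont$channels %in% spec$informative_channels
  inf_bd <- bands$name %in% spec$informative_bands

  gains <- exp(rnorm(spec$n_subjects, 0, spec$subject_variability))
  recs <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    trials <- vector("list", spec$n_trials)
    labels <- (seq_len(spec$n_trials) - 1L) %% spec$classes
    for (tr in seq_len(spec$n_trials)) {
      sig <- matrix(0, nch, nsig)
      base <- if (nbase > 0L) matrix(0, nch, nbase)
      for (b in seq_len(nrow(bands))) {
        sd_cell <- rep(spec$noise_sigma, nch)
        if (inf_bd[b])
          sd_cell[inf_ch] <- spec$noise_sigma *
            sqrt(spec$effect_size^labels[tr])
        sig <- sig + .band_noise(nch, nsig, spec$fs, bands$low[b],
                                 bands$high[b]) * sd_cell
        if (nbase > 0L)
          base <- base + .band_noise(nch, nbase, spec$fs, bands$low[b],
                                     bands$high[b]) * spec$noise_sigma
      }
      trials[[tr]] <- gains[s] * if (nbase > 0L) cbind(base, sig) else sig
    }
    ratings <- if (spec$classes == 2L)
      data.frame(valence = 3 + 4 * labels, arousal = 3 + 4 * labels,
                 dominance = 3 + 4 * labels, liking = 3 + 4 * labels)
    recs[[s]] <- eeg_recording(trials, fs = spec$fs, labels = labels,
                               baseline_seconds = spec$baseline_seconds,
                               channel_names = mont$channels,
                               ratings = ratings, subject = s)
  }
  cell_var <- vapply(seq_len(spec$classes) - 1L, function(cl) {
    v <- matrix(spec$noise_sigma^2, nch, nrow(bands),
                dimnames = list(mont$channels, bands$name))
    v[inf_ch, inf_bd] <- spec$noise_sigma^2 * spec$effect_size^cl
    v
  }, matrix(0, nch, nrow(bands)))
  structure(list(recordings = recs, spec = spec,
                 ground_truth = list(
                   informative_bands = spec$informative_bands,
                   informative_channels = spec$informative_channels,
                   class_cell_variance = cell_var,
                   subject_gains = gains)),
            class = "synth_dataset")
}

#' Write a synthetic dataset in an on-disk fixture layout
#'
#' `"deap"` pads the EEG channels with 8 all-zero non-EEG channels (so
#' channel selection on read is exercised) and stores 1-9 ratings;
#' `"seed"` writes per-trial channels x time matrices with categorical
#' labels; `"generic"` is seed without conventions.  All layouts are
#' plain text readable by [read_deap()] / [read_seed()].
#'
#' @param dataset a `synth_dataset`.
#' @param layout `"deap"`, `"seed"` or `"generic"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dataset, layout = c("deap", "seed", "generic"),
                          dir) {
  layout <- match.arg(layout)
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- dataset$spec
  recs <- dataset$recordings
  nch_eeg <- nrow(recs[[1L]]$signal[[1L]])
  if (layout == "deap") {
    pad <- 8L
    meta <- list(layout = "deap", fs = spec$fs,
                 n_subjects = length(recs),
                 n_channels = nch_eeg + pad, n_eeg = nch_eeg,
                 n_time = ncol(recs[[1L]]$signal[[1L]]),
                 baseline_seconds = spec$baseline_seconds,
                 channel_names = c(recs[[1L]]$channel_names,
                                   paste0("aux", seq_len(pad))))
    for (s in seq_along(recs)) {
      tag <- sprintf("s%02d", s)
      padded <- lapply(recs[[s]]$signal, function(m)
        rbind(m, matrix(0, pad, ncol(m))))
      .write_subject_matrix(padded,
                            file.path(dir, paste0(tag, "_data.csv")))
      ratings <- recs[[s]]$ratings %||%
        data.frame(valence = 3 + 4 * recs[[s]]$labels,
                   arousal = 3 + 4 * recs[[s]]$labels,
                   dominance = 3 + 4 * recs[[s]]$labels,
                   liking = 3 + 4 * recs[[s]]$labels)
      data.table::fwrite(ratings,
                         file.path(dir, paste0(tag, "_labels.csv")))
    }
  } else {
    meta <- list(layout = if (layout == "generic") "seed" else layout,
                 fs = spec$fs, n_subjects = length(recs),
                 n_channels = nch_eeg,
                 baseline_seconds = spec$baseline_seconds,
                 channel_names = recs[[1L]]$channel_names)
    for (s in seq_along(recs)) {
      tag <- sprintf("s%02d", s)
      for (tr in seq_along(recs[[s]]$signal)) {
        data.table::fwrite(
          data.table::as.data.table(recs[[s]]$signal[[tr]]),
          file.path(dir, sprintf("%s_t%02d.csv", tag, tr)),
          col.names = FALSE)
      }
      data.table::fwrite(data.frame(trial = seq_along(recs[[s]]$labels),
                                    label = recs[[s]]$labels),
                         file.path(dir, paste0(tag, "_labels.csv")))
    }
  }
  jsonlite::write_json(meta, .meta_path(dir), auto_unbox = TRUE,
                       digits = NA)
  # ground-truth sidecar for test assertions
  jsonlite::write_json(
    list(informative_bands = spec$informative_bands,
         informative_channels = spec$informative_channels,
         effect_size = spec$effect_size,
         subject_gains = dataset$ground_truth$subject_gains),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
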
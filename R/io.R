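# On-disk layouts are deliberately plain text so fixtures can ship with the
# package: numeric tables via data.table::fwrite/fread plus a JSON sidecar
# with shapes and metadata.  The "deap" layout mirrors the published
# per-subject array scheme (trials x 40 channels x time, first 32 channels
# EEG, 3 s baseline, 1-9 ratings on four scales); "seed" mirrors
# per-trial channels x time matrices of variable length with categorical
# labels; "generic" is the same with no padding conventions.

.meta_path <- function(dir) file.path(dir, "meta.json")

read_layout_meta <- function(dir) {
  if (!file.exists(.meta_path(dir)))
    stop("no meta.json in ", dir, call. = FALSE)
  jsonlite::read_json(.meta_path(dir), simplifyVector = TRUE)
}

# one row per trial, values channel-major (all samples of channel 1, then
# channel 2, ...)
.write_subject_matrix <- function(trials, path) {
  m <- t(vapply(trials, function(x) as.vector(t(x)),
                numeric(nrow(trials[[1L]]) * ncol(trials[[1L]]))))
  data.table::fwrite(data.table::as.data.table(m), path,
                     col.names = FALSE)
}

.read_subject_matrix <- function(path, nch, ntime) {
  m <- as.matrix(data.table::fread(path, header = FALSE))
  if (ncol(m) != nch * ntime)
    stop("shape mismatch in ", basename(path), ": expected ", nch, " x ",
         ntime, " = ", nch * ntime, " values per trial, found ", ncol(m),
         call. = FALSE)
  lapply(seq_len(nrow(m)), function(i) {
    matrix(m[i, ], nrow = nch, byrow = TRUE)
  })
}

#' Read a DEAP-layout fixture directory
#'
#' Expects `meta.json` plus, per subject, `sNN_data.csv` (one row per
#' trial, 40 channels x time flattened channel-major) and
#' `sNN_labels.csv` (valence, arousal, dominance, liking ratings, 1-9).
#' Only the first 32 channels (the EEG channels) are retained.
#'
#' @param dir fixture directory.
#' @param subject 1-based subject number.
#' @return an [eeg_recording()] with 32 channels, ratings attached and a
#'   3 s baseline.
#' @export
read_deap <- function(dir, subject = 1L) {
  meta <- read_layout_meta(dir)
  if (!identical(meta$layout, "deap"))
    stop("not a deap-layout directory (layout = ", meta$layout, ")",
         call. = FALSE)
  tag <- sprintf("s%02d", subject)
  trials <- .read_subject_matrix(file.path(dir, paste0(tag, "_data.csv")),
                                 meta$n_channels, meta$n_time)
  labf <- file.path(dir, paste0(tag, "_labels.csv"))
  if (!file.exists(labf))
    stop("missing labels file ", basename(labf), call. = FALSE)
  ratings <- utils::read.csv(labf)
  if (nrow(ratings) != length(trials))
    stop("labels rows (", nrow(ratings), ") != trials (", length(trials),
         ")", call. = FALSE)
  n_eeg <- meta$n_eeg %||% 32L   # leading channels are the EEG block
  eeg <- lapply(trials, function(m) m[seq_len(n_eeg), , drop = FALSE])
  eeg_recording(eeg, fs = meta$fs, baseline_seconds = meta$baseline_seconds,
                channel_names = meta$channel_names[seq_len(n_eeg)],
                ratings = ratings, subject = subject)
}

#' Read a SEED-layout fixture directory
#'
#' Expects `meta.json`, per-trial `sNN_tKK.csv` matrices (channels x time,
#' possibly different lengths) and `sNN_labels.csv` with a `label` column.
#'
#' @inheritParams read_deap
#' @return an [eeg_recording()] with categorical integer labels.
#' @export
read_seed <- function(dir, subject = 1L) {
  meta <- read_layout_meta(dir)
  if (!identical(meta$layout, "seed"))
    stop("not a seed-layout directory (layout = ", meta$layout, ")",
         call. = FALSE)
  tag <- sprintf("s%02d", subject)
  labf <- file.path(dir, paste0(tag, "_labels.csv"))
  if (!file.exists(labf))
    stop("missing labels file ", basename(labf), call. = FALSE)
  labels <- utils::read.csv(labf)$label
  trials <- lapply(seq_along(labels), function(k) {
    f <- file.path(dir, sprintf("%s_t%02d.csv", tag, k))
    if (!file.exists(f)) stop("missing trial file ", basename(f),
                              call. = FALSE)
    m <- as.matrix(data.table::fread(f, header = FALSE))
    if (nrow(m) != meta$n_channels)
      stop("shape mismatch in ", basename(f), ": ", nrow(m),
           " channels, expected ", meta$n_channels, call. = FALSE)
    unname(m)
  })
  eeg_recording(trials, fs = meta$fs, labels = as.integer(labels),
                baseline_seconds = meta$baseline_seconds %||% 0,
                channel_names = meta$channel_names, subject = subject)
}

#' Export a feature tensor as CSV
#'
#' Long-to-wide text serialization: one row per sample, one column per
#' (channel, band) cell named `channel.band`, plus trial/segment/label
#' columns, with band and channel names in a JSON sidecar.
#'
#' @param feat a `de_features` object.
#' @param path output CSV path (a `.json` sidecar is written next to it).
#' @export
write_features_csv <- function(feat, path) {
  d <- dim(feat$features)
  m <- matrix(feat$features, d[1L], d[2L] * d[3L])
  colnames(m) <- as.vector(outer(feat$channel_names, feat$band_names,
                                 paste, sep = "."))
  df <- data.table::data.table(feat$sample_index, m)
  if (!is.null(feat$labels)) df$label <- feat$labels
  data.table::fwrite(df, path)
  jsonlite::write_json(
    list(channel_names = feat$channel_names,
         band_names = feat$band_names,
         segment_seconds = feat$segment_seconds),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  df <- data.table::fread(path)
  idx_cols <- intersect(c("trial", "segment", "subject"), names(df))
  nch <- length(meta$channel_names)
  nb <- length(meta$band_names)
  cells <- as.vector(outer(meta$channel_names, meta$band_names,
                           paste, sep = "."))
  m <- as.matrix(df[, cells, with = FALSE])
  structure(list(
    features = array(m, c(nrow(m), nch, nb),
                     dimnames = list(NULL, meta$channel_names,
                                     meta$band_names)),
    sample_index = as.data.frame(df[, idx_cols, with = FALSE]),
    labels = if ("label" %in% names(df)) df$label else NULL,
    band_names = meta$band_names, channel_names = meta$channel_names,
    segment_seconds = meta$segment_seconds), class = "de_features")
}
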
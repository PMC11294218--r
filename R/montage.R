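#' Electrode montage
#'
#' A montage is an ordered set of electrode labels with 3-D positions in a
#' common, montage-native length unit (the bundled montages use an idealized
#' unit-radius spherical head).  Channel order in the montage is the channel
#' order of all data arrays fed to the model.
#'
#' @param channels character vector of unique channel labels (>= 2).
#' @param coords numeric matrix, one row per channel, columns x, y, z
#'   (x = right, y = front, z = up).
#' @return an object of class `eeg_montage` with elements `channels` and
#'   `coords`.
#' @examples
#' m <- montage(c("A", "B"), rbind(c(0, 0, 0), c(1, 0, 0)))
#' m$channels
#' @export
montage <- function(channels, coords) {
  channels <- as.character(channels)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(channels) < 2L)
    stop("a montage needs at least 2 channels", call. = FALSE)
  if (anyDuplicated(channels))
    stop("duplicate channel labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "),
         call. = FALSE)
  if (nrow(coords) != length(channels) || ncol(coords) != 3L)
    stop("coords must be a ", length(channels), " x 3 matrix", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("montage coordinates must be finite", call. = FALSE)
  dimnames(coords) <- list(channels, c("x", "y", "z"))
  structure(list(channels = channels, coords = coords),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channels), " channels: ",
      paste(head(x$channels, 6L), collapse = ", "),
      if (length(x$channels) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a montage from CSV
#'
#' Expects a header `name,x,y,z`; row order defines channel order.
#'
#' @param path CSV file path.
#' @return an [montage()] object.
#' @export
read_montage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("montage file must have columns name,x,y,z", call. = FALSE)
  montage(df$name, as.matrix(df[, c("x", "y", "z")]))
}

# ---- idealized 10-20 / 10-10 spherical positions -------------------------
# Unit-radius head model: electrode at inclination a (degrees from vertex
# Cz) and azimuth t (degrees from the front midline, positive to the
# right): x = sin a sin t, y = sin a cos t, z = cos a.  Lateral electrodes
# are placed by great-circle interpolation between the midline anchor of
# their row and the corresponding 10% ring electrode, the classical
# idealization used when measured positions are unavailable.

.sph_point <- function(incl, azim) {
  a <- incl * pi / 180
  t <- azim * pi / 180
  c(sin(a) * sin(t), sin(a) * cos(t), cos(a))
}

.slerp <- function(p, q, t) {
  w <- acos(max(-1, min(1, sum(p * q))))
  (sin((1 - t) * w) * p + sin(t * w) * q) / sin(w)
}

# full label -> xyz table for the 10-10 subset used by the bundled montages
.standard_positions <- function() {
  pos <- list(
    FPZ = .sph_point(90, 0),   AFZ = .sph_point(72, 0),
    FZ  = .sph_point(54, 0),   FCZ = .sph_point(36, 0),
    CZ  = .sph_point(0, 0),    CPZ = .sph_point(36, 180),
    PZ  = .sph_point(54, 180), POZ = .sph_point(72, 180),
    OZ  = .sph_point(90, 180)
  )
  # 10% ring at inclination 90, azimuths in 18-degree steps from FPZ
  ring <- c(FP = 18, AF = 36, F = 54, FT = 72, T = 90,
            TP = 108, P = 126, PO = 144, O = 162)
  for (row in names(ring)) {
    pos[[paste0(row, "2_RING")]] <- .sph_point(90, ring[[row]])
    pos[[paste0(row, "1_RING")]] <- .sph_point(90, -ring[[row]])
  }
  # conventional ring names
  pos$FP2 <- pos$FP2_RING; pos$FP1 <- pos$FP1_RING
  pos$AF8 <- pos$AF2_RING; pos$AF7 <- pos$AF1_RING
  pos$F8  <- pos$F2_RING;  pos$F7  <- pos$F1_RING
  pos$FT8 <- pos$FT2_RING; pos$FT7 <- pos$FT1_RING
  pos$T8  <- pos$T2_RING;  pos$T7  <- pos$T1_RING
  pos$TP8 <- pos$TP2_RING; pos$TP7 <- pos$TP1_RING
  pos$P8  <- pos$P2_RING;  pos$P7  <- pos$P1_RING
  pos$PO8 <- pos$PO2_RING; pos$PO7 <- pos$PO1_RING
  pos$O2  <- pos$O2_RING;  pos$O1  <- pos$O1_RING
  # lateral rows: interpolate midline anchor -> ring electrode
  lat <- function(mid, ringlab, labels, fracs) {
    p <- pos[[mid]]; q <- pos[[ringlab]]
    out <- list()
    for (i in seq_along(labels)) out[[labels[i]]] <- .slerp(p, q, fracs[i])
    out
  }
  rows <- c(
    lat("AFZ", "AF7", c("AF3"), 0.5),
    lat("AFZ", "AF8", c("AF4"), 0.5),
    lat("FZ",  "F7",  c("F1", "F3", "F5"), c(.25, .5, .75)),
    lat("FZ",  "F8",  c("F2", "F4", "F6"), c(.25, .5, .75)),
    lat("FCZ", "FT7", c("FC1", "FC3", "FC5"), c(.25, .5, .75)),
    lat("FCZ", "FT8", c("FC2", "FC4", "FC6"), c(.25, .5, .75)),
    lat("CZ",  "T7",  c("C1", "C3", "C5"), c(.25, .5, .75)),
    lat("CZ",  "T8",  c("C2", "C4", "C6"), c(.25, .5, .75)),
    lat("CPZ", "TP7", c("CP1", "CP3", "CP5"), c(.25, .5, .75)),
    lat("CPZ", "TP8", c("CP2", "CP4", "CP6"), c(.25, .5, .75)),
    lat("PZ",  "P7",  c("P1", "P3", "P5"), c(.25, .5, .75)),
    lat("PZ",  "P8",  c("P2", "P4", "P6"), c(.25, .5, .75)),
    lat("POZ", "PO7", c("PO3", "PO5"), c(1 / 3, 2 / 3)),
    lat("POZ", "PO8", c("PO4", "PO6"), c(1 / 3, 2 / 3))
  )
  pos <- c(pos, rows)
  # cerebellar leads sit below the ring, same azimuth as O1/O2
  pos$CB1 <- .sph_point(108, -162)
  pos$CB2 <- .sph_point(108, 162)
  pos <- pos[!grepl("_RING$", names(pos))]
  mat <- do.call(rbind, pos)
  colnames(mat) <- c("x", "y", "z")
  mat
}

.deap32_names <- c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
  "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
  "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
  "PO4", "O2")

.seed62_names <- c(
  "FP1", "FPZ", "FP2", "AF3", "AF4", "F7", "F5", "F3", "F1", "FZ",
  "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2",
  "FC4", "FC6", "FT8", "T7", "C5", "C3", "C1", "CZ", "C2", "C4",
  "C6", "T8", "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6",
  "TP8", "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8", "CB1", "O1", "OZ",
  "O2", "CB2")

#' Load a bundled standard montage (or a user CSV)
#'
#' `"deap32"` is the 32-EEG-channel layout of 128 Hz consumer-grade
#' recordings in the standard Geneva channel order; `"seed62"` is the
#' 62-channel research cap order.  Coordinates are idealized 10-20/10-10
#' positions on a unit sphere (a synthetic stand-in for measured
#' positions).  Any other value is treated as a path to a `name,x,y,z` CSV.
#'
#' @param name `"deap32"`, `"seed62"`, or a CSV path.
#' @return an [montage()] object in dataset channel order.
#' @export
load_standard_montage <- function(name) {
  if (identical(name, "deap32") || identical(name, "seed62")) {
    tab <- .standard_positions()
    labels <- if (name == "deap32") .deap32_names else .seed62_names
    idx <- match(toupper(labels), toupper(rownames(tab)))
    if (anyNA(idx))
      stop("internal montage table is missing: ",
           paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
    return(montage(labels, tab[idx, , drop = FALSE]))
  }
  if (!file.exists(name))
    stop("unknown montage '", name,
         "' (expected \"deap32\", \"seed62\", or a CSV file path)",
         call. = FALSE)
  read_montage_csv(name)
}
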
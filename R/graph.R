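#' Electrode-distance adjacency
#'
#' Builds the fixed geometric graph the graph-convolution block propagates
#' over.  Edge weights are inverse Euclidean 3-D distances between
#' electrodes, w_ij = 1 / d_ij for i != j, and the diagonal is exactly 1.
#' Distances are taken in the montage's native units; no rescaling is
#' applied (any monotone rescale would change the weights).
#'
#' @param mont an [montage()] object.
#' @return an object of class `electrode_graph` with elements `adjacency`,
#'   `distances`, `propagation` (`NULL` until [normalize_propagation()] is
#'   called) and `channel_names`.
#' @examples
#' g <- build_adjacency(montage(c("A", "B"), rbind(c(0, 0, 0), c(1, 0, 0))))
#' g$adjacency
#' @export
build_adjacency <- function(mont) {
  stopifnot(inherits(mont, "eeg_montage"))
  d <- as.matrix(stats::dist(mont$coords))
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    idx <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1L, ]
    stop(structure(class = c("damgcn_coincident_electrodes", "error",
                             "condition"),
                   list(message = paste0(
                     "coincident electrodes: '", mont$channels[idx[1L]],
                     "' and '", mont$channels[idx[2L]],
                     "' share identical coordinates"),
                     call = NULL)))
  }
  a <- 1 / d
  diag(a) <- 1
  dimnames(a) <- dimnames(d) <- list(mont$channels, mont$channels)
  structure(list(adjacency = a, distances = d, propagation = NULL,
                 channel_names = mont$channels),
            class = "electrode_graph")
}

#' Symmetrically normalized propagation matrix
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal degree
#' matrix of the self-looped adjacency.  Because the adjacency already
#' carries a unit diagonal and the identity is added again, the self-looped
#' matrix has diagonal 2 by default; `single_self_loop = TRUE` skips the
#' extra identity (ablation of that quirk).
#'
#' @param graph an `electrode_graph` from [build_adjacency()].
#' @param single_self_loop logical; if `TRUE` do not add the identity a
#'   second time.
#' @return the graph with `propagation` filled in (symmetric, spectral
#'   radius <= 1).
#' @export
normalize_propagation <- function(graph, single_self_loop = FALSE) {
  stopifnot(inherits(graph, "electrode_graph"))
  at <- graph$adjacency
  if (!single_self_loop) at <- at + diag(nrow(at))
  deg <- rowSums(at)
  stopifnot(all(deg > 0))  # guaranteed by the unit diagonal
  s <- 1 / sqrt(deg)
  p <- at * (s %o% s)
  p <- (p + t(p)) / 2  # remove floating-point asymmetry
  dimnames(p) <- dimnames(graph$adjacency)
  graph$propagation <- p
  graph$single_self_loop <- single_self_loop
  graph
}

#' Build the full electrode graph for a montage
#'
#' Convenience wrapper: [build_adjacency()] then [normalize_propagation()].
#'
#' @inheritParams build_adjacency
#' @inheritParams normalize_propagation
#' @export
electrode_graph <- function(mont, single_self_loop = FALSE) {
  normalize_propagation(build_adjacency(mont), single_self_loop)
}

#' @export
print.electrode_graph <- function(x, ...) {
  cat("<electrode_graph> ", nrow(x$adjacency), " channels, propagation ",
      if (is.null(x$propagation)) "not yet normalized" else "ready",
      "\n", sep = "")
  invisible(x)
}

#' Export a graph matrix as TSV
#'
#' Square matrix with channel names as header row and first column.
#'
#' @param graph an `electrode_graph`.
#' @param path output file.
#' @param what one of `"adjacency"`, `"distances"`, `"propagation"`.
#' @export
write_graph_tsv <- function(graph, path,
                            what = c("adjacency", "distances",
                                     "propagation")) {
  what <- match.arg(what)
  m <- graph[[what]]
  if (is.null(m)) stop(what, " has not been computed", call. = FALSE)
  df <- data.table::data.table(channel = rownames(m), m)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
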
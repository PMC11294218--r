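# Shared fixture builders.  Everything is generated in code; sizes are
# deliberately tiny so the default suite stays fast -- the acceptance
# tests exercise the published scales.

# 8-electrode subset of the 32-channel montage (keeps F3/O1 so planted
# channel recovery has realistic neighbours)
tiny_montage <- function() {
  mont <- load_standard_montage("deap32")
  keep <- c("Fp1", "F3", "C3", "T7", "P3", "O1", "Fz", "Cz")
  montage(keep, mont$coords[match(keep, mont$channels), ])
}

tiny_graph <- function() electrode_graph(tiny_montage())

# small but learnable model configuration
tiny_config <- function(...) {
  damgcn_config(num_channels = 8, num_bands = 4, num_classes = 2,
                embedding = 32, encoders = 1, heads = 4, dropout = 0.5,
                ...)
}

# gradient-check sized configuration (dropout off so finite differences
# are well-defined)
grad_config <- function(...) {
  damgcn_config(num_channels = 4, num_bands = 3, num_classes = 2,
                embedding = 8, encoders = 1, heads = 2, dropout = 0,
                ...)
}

random_montage <- function(n, seed = 1) {
  set.seed(seed)
  montage(paste0("e", seq_len(n)), matrix(rnorm(3 * n), n))
}

# synthetic world with class signal planted in gamma at F3 and O1
tiny_synth <- function(seed = 1, n_trials = 12, trial_seconds = 11,
                       effect_size = 4) {
  synth_spec(n_subjects = 1, n_trials = n_trials,
             trial_seconds = trial_seconds, baseline_seconds = 1,
             fs = 128, montage = tiny_montage(),
             bands = eeg_bands("deap"), informative_bands = "gamma",
             informative_channels = c("F3", "O1"),
             effect_size = effect_size, subject_variability = 0.2,
             seed = seed)
}

tiny_features <- function(seed = 1, ...) {
  ds <- synth_generate(tiny_synth(seed = seed, ...))
  extract_features(ds$recordings[[1]], eeg_bands("deap"),
                   segment_seconds = 1)
}

# walk a parameter tree and return integer index paths of all leaves
param_leaf_paths <- function(tree) {
  paths <- list()
  walk <- function(p, prefix) {
    if (is.list(p)) {
      for (i in seq_along(p)) walk(p[[i]], c(prefix, i))
    } else {
      paths[[length(paths) + 1L]] <<- prefix
    }
  }
  walk(tree, integer())
  paths
}

tree_get <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}

tree_set <- function(tree, path, val) {
  if (length(path) == 1L) {
    tree[[path]] <- val
    return(tree)
  }
  tree[[path[1L]]] <- tree_set(tree[[path[1L]]], path[-1L], val)
  tree
}
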
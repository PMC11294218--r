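test_that("generation is exactly reproducible from the seed", {
  s <- tiny_synth(seed = 8, n_trials = 2, trial_seconds = 3)
  d1 <- synth_generate(s)
  d2 <- synth_generate(s)
  expect_identical(d1$recordings[[1]]$signal, d2$recordings[[1]]$signal)
  expect_identical(d1$ground_truth$subject_gains,
                   d2$ground_truth$subject_gains)
})

test_that("planted DE separation matches the closed form", {
  # effect 4 in gamma cells: DE gap per class step = 0.5 * log(4)
  spec <- tiny_synth(seed = 13, n_trials = 20, trial_seconds = 11)
  ds <- synth_generate(spec)
  feat <- extract_features(ds$recordings[[1]], eeg_bands("deap"),
                           segment_seconds = 1)
  de_gamma <- feat$features[, "F3", "gamma"]
  gap <- mean(de_gamma[feat$labels == 1]) -
    mean(de_gamma[feat$labels == 0])
  n1 <- sum(feat$labels == 1)
  se <- sqrt(var(de_gamma[feat$labels == 1]) / n1 +
               var(de_gamma[feat$labels == 0]) / n1)
  expect_lt(abs(gap - 0.5 * log(4)), 3 * se + 0.02)

  # uninformative cells have no gap
  de_theta <- feat$features[, "C3", "theta"]
  gap0 <- mean(de_theta[feat$labels == 1]) -
    mean(de_theta[feat$labels == 0])
  expect_lt(abs(gap0), 0.1)

  # absolute level matches 0.5 * log(2 pi e sigma^2 * gain^2)
  gain <- ds$ground_truth$subject_gains[1]
  expect_equal(mean(de_theta),
               0.5 * log(2 * pi * exp(1) * gain^2), tolerance = 0.05)
})

test_that("a null world (effect 1) carries no class signal", {
  spec <- tiny_synth(seed = 17, n_trials = 12, trial_seconds = 9,
                     effect_size = 1)
  ds <- synth_generate(spec)
  feat <- extract_features(ds$recordings[[1]], eeg_bands("deap"),
                           segment_seconds = 1)
  # DE distributions identical across classes in the "informative" cell
  g1 <- feat$features[feat$labels == 1, "F3", "gamma"]
  g0 <- feat$features[feat$labels == 0, "F3", "gamma"]
  expect_gt(stats::t.test(g1, g0)$p.value, 1e-3)
  # trained accuracy sits at chance
  sp <- kfold_splits(feat$labels, k = 5, seed = 3)
  res <- cv_evaluate(feat$features, feat$labels, sp, tiny_graph(),
                     damgcn_config(8, 4, 2, embedding = 16,
                                   encoders = 1, heads = 2,
                                   dropout = 0.3, gcn_layers = 1),
                     train_config(max_epochs = 20, batch_size = 32,
                                  patience = 8, seed = 7))
  spread <- max(sd(res$fold_accuracy), 0.02)
  expect_lte(abs(res$mean_accuracy - 0.5), 3 * spread)
})

test_that("fixture layouts round-trip through the readers", {
  dir <- tempfile("fix")
  spec <- tiny_synth(seed = 23, n_trials = 3, trial_seconds = 2)
  ds <- synth_generate(spec)

  # deap layout: 8 zero aux channels appended, ratings written
  write_fixture(ds, "deap", dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$n_channels, 8 + 8)
  rec <- read_deap(dir, 1)
  # readers keep only the leading EEG block, dropping the zero padding
  expect_equal(nrow(rec$signal[[1]]), meta$n_eeg)
  expect_equal(rec$signal[[1]], ds$recordings[[1]]$signal[[1]],
               tolerance = 1e-12, ignore_attr = TRUE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_identical(gt$informative_bands, "gamma")

  # seed layout: per-trial matrices, labels, exact round trip
  dir2 <- tempfile("fix")
  write_fixture(ds, "seed", dir2)
  rec2 <- read_seed(dir2, 1)
  expect_equal(length(rec2$signal), 3)
  expect_equal(rec2$labels, ds$recordings[[1]]$labels)
  expect_equal(rec2$signal[[2]], ds$recordings[[1]]$signal[[2]],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rec2$fs, 128)

  # mangled fixtures produce shape errors
  files <- list.files(dir2, "t02", full.names = TRUE)
  writeLines("1,2,3", files[1])
  expect_error(read_seed(dir2, 1), "shape mismatch")
  expect_error(read_deap(dir2, 1), "not a deap-layout")
})

test_that("deap-layout readers recover the ratings for binarization", {
  dir <- tempfile("fix")
  ds <- synth_generate(tiny_synth(seed = 29, n_trials = 4,
                                  trial_seconds = 2))
  write_fixture(ds, "deap", dir)
  rec <- read_deap(dir, 1)
  y <- binarize_deap_labels(rec$ratings, "valence")
  expect_identical(y, ds$recordings[[1]]$labels)
})

test_that("feature tensors round-trip through CSV", {
  feat <- tiny_features(seed = 37, n_trials = 2, trial_seconds = 3)
  f <- tempfile(fileext = ".csv")
  write_features_csv(feat, f)
  back <- read_features_csv(f)
  expect_equal(back$features, feat$features, tolerance = 1e-12)
  expect_identical(back$labels, feat$labels)
  expect_identical(back$band_names, feat$band_names)
})

test_that("spec validation rejects inconsistent worlds", {
  expect_error(tiny_synth_bad <- synth_spec(informative_bands = "delta",
                                            bands = eeg_bands("deap")),
               "informative_bands")
  expect_error(synth_spec(informative_channels = "NOPE"),
               "informative_channels")
  expect_error(synth_spec(fs = 16, bands = eeg_bands("deap")),
               "Nyquist")
})

test_that("the CLI wires synth, training and interpretation together", {
  dir <- tempfile("cli")
  spec_file <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(n_subjects = 1, n_trials = 6, trial_seconds = 5,
         baseline_seconds = 1, fs = 128, montage = "deap32",
         informative_channels = c("F3", "O1"), effect_size = 4,
         seed = 5),
    spec_file, auto_unbox = TRUE)
  expect_invisible(damgcn_cli(c("synth", "--spec", spec_file,
                                "--layout", "seed", "--out", dir)))
  expect_true(file.exists(file.path(dir, "meta.json")))
  rec <- read_seed(dir, 1)
  expect_equal(length(rec$signal), 6)
})
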
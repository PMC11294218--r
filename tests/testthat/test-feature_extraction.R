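test_that("segmentation follows the floor rule and drops the baseline", {
  fs <- 128
  trial <- matrix(rnorm(2 * 63 * fs), 2)          # 63 s, 2 channels
  segs <- segment_trial(trial, fs, segment_seconds = 0.5,
                        baseline_seconds = 3)
  expect_length(segs, 120)
  expect_equal(ncol(segs[[1]]), 64)
  # contiguity: first segment starts right after the baseline
  expect_identical(segs[[1]], trial[, (3 * fs + 1):(3 * fs + 64)])

  segs2 <- segment_trial(matrix(rnorm(120 * 100), 1), 100, 1)
  expect_length(segs2, 120)

  # 10.7 s usable at 1 s windows -> 10 segments, 0.7 s dropped
  segs3 <- segment_trial(matrix(rnorm(1070), 1), 100, 1)
  expect_length(segs3, 10)

  expect_warning(segment_trial(matrix(rnorm(50), 1), 100, 1),
                 "shorter than one segment")
})

test_that("differential entropy matches its closed form", {
  # unit variance: 0.5 * log(2 pi e)
  expect_equal(de_from_variance(1), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  # the zero of the closed form
  expect_equal(de_from_variance(1 / (2 * pi * exp(1))), 0,
               tolerance = 1e-12)
  # zero variance is floored, never -Inf
  expect_true(is.finite(differential_entropy(rep(3, 100))))
  expect_equal(differential_entropy(rep(3, 100)),
               de_from_variance(1e-12))

  # Monte-Carlo draw, sigma = 2
  set.seed(42)
  x <- rnorm(1e5, sd = 2)
  expect_equal(differential_entropy(x),
               0.5 * log(2 * pi * exp(1) * 4), tolerance = 0.01)

  # quadrature oracle on the defining integral for N(0, 4)
  integrand <- function(t) {
    v <- dnorm(t, sd = 2)
    ifelse(v > 0, -v * log(v), 0)
  }
  h_num <- stats::integrate(integrand, -40, 40, rel.tol = 1e-10)$value
  expect_equal(h_num, 0.5 * log(2 * pi * exp(1) * 4), tolerance = 1e-6)
})

test_that("DE is monotone in variance, shift-invariant, log-scaling", {
  set.seed(7)
  for (i in 1:20) {
    v <- sort(runif(2, 0.01, 10))
    expect_lt(de_from_variance(v[1]), de_from_variance(v[2]))
  }
  x <- rnorm(500)
  expect_lt(abs(differential_entropy(x + 17.3) -
                  differential_entropy(x)), 1e-9)
  s <- 3.7
  expect_equal(differential_entropy(s * x),
               differential_entropy(x) + log(abs(s)), tolerance = 1e-9)
})

test_that("band decomposition isolates energy where it belongs", {
  fs <- 200
  n <- 2 * fs
  t <- seq_len(n) / fs
  sine <- matrix(sin(2 * pi * 10 * t), 1)          # 10 Hz -> alpha
  out <- band_decompose(sine, fs, eeg_bands("seed"))
  energy <- apply(out, 2, function(m) sum(m^2))
  names(energy) <- eeg_bands("seed")$name
  expect_gte(energy[["alpha"]] / sum(sine^2), 0.95)

  expect_equal(band_decompose(matrix(0, 2, n), fs, eeg_bands("seed")),
               array(0, c(2, 5, n)), ignore_attr = TRUE)

  # flat-spectrum oracle: white-noise band variance tracks band width
  set.seed(1)
  wn <- matrix(rnorm(4 * 2000), 4)
  spec <- eeg_bands("seed")
  dec <- suppressWarnings(band_decompose(wn, 100, spec))  # gamma clipped
  v <- apply(dec, 2, var)
  frac <- vapply(seq_len(nrow(spec)),
                 function(b) (min(spec$high[b], 50) - spec$low[b]) / 50,
                 0)
  expect_equal(colMeans(matrix(apply(dec, c(1, 2), var), 4)), frac,
               tolerance = 0.15, ignore_attr = TRUE)
})

test_that("bands above Nyquist are clipped with a warning", {
  expect_warning(band_decompose(matrix(rnorm(256), 1), 64,
                                eeg_bands("seed")),
                 "exceed Nyquist")
  # a band entirely above Nyquist is an error
  suppressWarnings(expect_error(clip_bands(band_spec("hf", 40, 60), 64),
                                "entirely above Nyquist"))
})

test_that("extract_features composes segment/band/DE with exact shapes", {
  ds <- synth_generate(tiny_synth(seed = 5, n_trials = 3,
                                  trial_seconds = 4))
  rec <- ds$recordings[[1]]
  feat <- extract_features(rec, eeg_bands("deap"), segment_seconds = 1)
  expect_equal(dim(feat$features), c(9, 8, 4))  # 3 trials x 3 usable s
  expect_identical(feat$band_names, eeg_bands("deap")$name)
  expect_true(all(is.finite(feat$features)))
  # sample labels equal their trial's label
  expect_identical(feat$labels,
                   rep(as.integer(rec$labels), each = 3))
  # single 1 s trial -> 1 x C x F
  rec1 <- eeg_recording(list(matrix(rnorm(8 * 128), 8)), fs = 128)
  f1 <- extract_features(rec1, eeg_bands("deap"), segment_seconds = 1)
  expect_equal(dim(f1$features), c(1, 8, 4))
})

test_that("sample counts obey the floor formula for random durations", {
  set.seed(11)
  fs <- 64
  durations <- sample(50:400, 6)                   # in samples
  trials <- lapply(durations, function(d) matrix(rnorm(2 * d), 2))
  rec <- eeg_recording(trials, fs = fs, labels = rep(0L, 6),
                       baseline_seconds = 0.25)
  feat <- suppressWarnings(
    extract_features(rec, band_spec(c("lo", "hi"), c(1, 8), c(8, 30)),
                     segment_seconds = 0.5))
  # naive loop oracle
  expected <- sum(vapply(durations, function(d) {
    (d - 16) %/% 32
  }, numeric(1)))
  expect_equal(dim(feat$features)[1], expected)
})

test_that("stft band variances agree with the filter route in expectation", {
  set.seed(3)
  rec <- eeg_recording(list(matrix(rnorm(2 * 128 * 20), 2)), fs = 128)
  spec <- eeg_bands("deap")
  f1 <- extract_features(rec, spec, 1, method = "filter")
  f2 <- extract_features(rec, spec, 1, method = "stft")
  expect_equal(dim(f2$features), dim(f1$features))
  # same band variances on average (white input, stationary); the Hann
  # window costs resolution in the narrow bands, so compare loosely
  expect_lt(mean(abs(colMeans(matrix(f2$features, 20)) -
                       colMeans(matrix(f1$features, 20)))), 0.15)
})

test_that("rating binarization is strict at the threshold", {
  expect_identical(binarize_deap_labels(c(7, 5, 1, 5.1), "valence"),
                   c(1L, 0L, 0L, 1L))
  expect_identical(binarize_deap_labels(5, "valence", strict = FALSE), 1L)
  df <- data.frame(valence = c(2, 8), arousal = c(6, 4))
  expect_identical(binarize_deap_labels(df, "arousal"), c(1L, 0L))
  expect_error(binarize_deap_labels(c(0.5, 3), "valence"), "\\[1, 9\\]")
  expect_error(binarize_deap_labels(10, "valence"), "\\[1, 9\\]")
})

test_that("bind_features stacks subjects and tracks provenance", {
  f1 <- tiny_features(seed = 1, n_trials = 2, trial_seconds = 3)
  f2 <- tiny_features(seed = 2, n_trials = 2, trial_seconds = 3)
  b <- bind_features(list(f1, f2), subjects = c("s1", "s2"))
  expect_equal(dim(b$features)[1],
               dim(f1$features)[1] + dim(f2$features)[1])
  expect_identical(unique(b$sample_index$subject), c("s1", "s2"))
  expect_equal(b$features[1, , ], f1$features[1, , ])
})
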
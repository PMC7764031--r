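# Synthetic EEG generator: determinism, spectra, planted effects,
# clone fixtures.

test_that("generation is bit-identical under one seed and differs across seeds", {
  cfg <- small_synth(seed = 7)
  a <- synth_generate(cfg)
  b <- synth_generate(cfg)
  expect_identical(a$recordings[[1]]$data, b$recordings[[1]]$data)
  expect_identical(a$ratings, b$ratings)
  c <- synth_generate(small_synth(seed = 8))
  expect_false(identical(a$recordings[[1]]$data, c$recordings[[1]]$data))
})

test_that("generated recordings satisfy the recording invariants and round-trip", {
  gen <- synth_generate(small_synth(seed = 19))
  rec <- gen$recordings[[1]]
  expect_s3_class(validate_recording(rec), "eeg_recording")
  p <- withr::local_tempfile(fileext = ".h5")
  write_eeg_h5(rec, p)
  expect_identical(read_eeg_h5(p)$data, rec$data)
})

test_that("ratings binarize back to the latent classes exactly", {
  gen <- synth_generate(synth_config(n_subjects = 2, n_trials_per_subject = 6,
                                     trial_seconds = 2, baseline_seconds = 0,
                                     seed = 23))
  for (emo in c("valence", "arousal")) {
    labs <- binarize_ratings(gen$ratings, emo)
    expect_identical(labs$label, gen$labels[[emo]])
  }
  # classes are balanced within subject
  expect_identical(as.integer(tapply(gen$labels$valence, gen$labels$subject, sum)),
                   c(3L, 3L))
})

test_that("an alpha-only configuration concentrates its spectrum in 8-12 Hz", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 2,
                      trial_seconds = 8, baseline_seconds = 0,
                      band_amplitudes = c(theta = 0, alpha = 10, beta = 0, gamma = 0),
                      one_over_f_amplitude = 0.5, background_noise_sd = 0.2,
                      effect = list(), seed = 29)
  gen <- synth_generate(cfg)
  x <- gen$recordings[[1]]$data[1, 1, ]
  fs <- cfg$fs
  in_band <- fft_band_power(x, fs, 8, 12)
  total <- fft_band_power(x, fs, 4, 47)
  expect_gt(in_band / total, 0.8)
})

test_that("a planted amplitude effect shows the expected band-power ratio", {
  # amplitude x2 on class-1 trials -> in-band power x4, measured on the raw
  # signals with a direct FFT (independent of the package's filters)
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 12,
                      trial_seconds = 8, baseline_seconds = 0,
                      effect = list(list(channel = "P8", band = "alpha",
                                         amplitude_ratio = 2)),
                      seed = 37)
  gen <- synth_generate(cfg)
  rec <- gen$recordings[[1]]
  cls <- gen$labels$valence
  p8 <- match("P8", rec$channel_names)
  pow <- vapply(seq_len(n_trials(rec)), function(tr)
    fft_band_power(rec$data[tr, p8, ], cfg$fs, 8, 12), 0)
  ratio <- mean(pow[cls == 1]) / mean(pow[cls == 0])
  expect_gt(ratio, 2.6)
  expect_lt(ratio, 6)
  # a control channel far from the effect shows no such shift
  cz <- match("O2", rec$channel_names)
  pow0 <- vapply(seq_len(n_trials(rec)), function(tr)
    fft_band_power(rec$data[tr, cz, ], cfg$fs, 8, 12), 0)
  ratio0 <- mean(pow0[cls == 1]) / mean(pow0[cls == 0])
  expect_lt(abs(log(ratio0)), log(2))
})

test_that("with unit amplitude ratio the classes are indistinguishable", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 10,
                      trial_seconds = 10, baseline_seconds = 0,
                      effect = list(list(channel = "P8", band = "alpha",
                                         amplitude_ratio = 1)),
                      seed = 41)
  gen <- synth_generate(cfg)
  fm <- build_feature_matrix(gen$recordings[[1]])
  y <- broadcast_labels(fm, binarize_ratings(gen$ratings, "valence"))
  pvals <- apply(fm$values, 2, function(v) t.test(v[y == 0], v[y == 1])$p.value)
  # no feature survives multiplicity control under the constructed null
  expect_true(all(p.adjust(pvals, "BH") > 0.01))
})

test_that("config validation names the offending field", {
  expect_error(synth_config(n_trials_per_subject = 5), "even")
  expect_error(synth_config(effect = list(list(channel = "XX", band = "alpha",
                                               amplitude_ratio = 2))),
               "unknown channel 'XX'")
  expect_error(synth_config(effect = list(list(channel = "P8", band = "delta",
                                               amplitude_ratio = 2))),
               "unknown band 'delta'")
  expect_error(synth_config(effect = list(list(channel = "P8", band = "alpha",
                                               amplitude_ratio = -1))),
               "amplitude_ratio")
  expect_error(synth_config(redundancy_groups = list(
    list(channels = c("P8", "QQ"), weight = 0.5))), "QQ")
})

test_that("clone fixtures have exact-orthogonal references and tight clone groups", {
  m <- make_clone_matrix(300, list(g1 = c("a1", "a2", "a3"),
                                   g2 = c("b1", "b2", "b3"),
                                   r1 = "x", r2 = "y"),
                         noise_sd = 0.05, seed = 3)
  C <- cor(m$values)
  expect_gt(min(abs(C[c("a1", "a2", "a3"), c("a1", "a2", "a3")])), 0.99)
  expect_lt(max(abs(C[c("a1", "a2", "a3"), c("b1", "b2", "b3")])), 0.2)
  # reference columns are exactly sample-decorrelated by construction
  expect_equal(C["x", "y"], 0, tolerance = 1e-12)
  # selection recovers exactly the reference columns
  expect_setequal(rca_select(m, 2)$selected, c("x", "y"))
  # a single clone of a singleton group comes back unchanged in shape
  m1 <- make_clone_matrix(50, list(only = "z"), 0, seed = 4)
  expect_identical(colnames(m1$values), "z")
  # determinism
  m2 <- make_clone_matrix(300, list(g1 = c("a1", "a2", "a3"),
                                    g2 = c("b1", "b2", "b3"),
                                    r1 = "x", r2 = "y"),
                          noise_sd = 0.05, seed = 3)
  expect_identical(m$values, m2$values)
})
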
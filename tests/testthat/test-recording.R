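# Recording model, preprocessing and file interchange.

test_that("recording construction validates shape, names and finiteness", {
  x <- array(rnorm(2 * 3 * 128), c(2, 3, 128))
  rec <- eeg_recording(x, c("Fz", "Cz", "Pz"), 128)
  expect_s3_class(rec, "eeg_recording")
  expect_identical(n_trials(rec), 2L)

  expect_error(eeg_recording(x, c("Fz", "Cz"), 128), "channel_names")
  expect_error(eeg_recording(x, c("Fz", "Cz", "Cz"), 128), "unique")

  x[2, 3, 5] <- NaN
  err <- expect_error(eeg_recording(x, c("Fz", "Cz", "Pz"), 128))
  expect_match(conditionMessage(err), "trial 2")
  expect_match(conditionMessage(err), "Pz")
})

test_that("baseline trimming removes exactly the pre-trial samples and is idempotent", {
  fs <- 128
  x <- array(rnorm(2 * 2 * 63 * fs), c(2, 2, 63 * fs))
  rec <- eeg_recording(x, c("Cz", "Pz"), fs, baseline_seconds = 3)
  out <- trim_baseline(rec)
  expect_identical(dim(out$data)[3], as.integer(60 * fs))
  expect_identical(out$baseline_seconds, 0)
  expect_identical(out$data[1, 1, ], x[1, 1, -(1:(3 * fs))])
  # second call is the identity
  expect_identical(trim_baseline(out), out)
  # baseline longer than the trial is rejected
  expect_error(
    eeg_recording(array(0, c(1, 1, 4 * fs)), "Cz", fs, baseline_seconds = 5),
    "baseline")
})

test_that("downsampling preserves structure and spectral content", {
  fs <- 512
  t <- (0:(fs * 4 - 1)) / fs
  x <- array(0, c(2, 2, length(t)))
  for (tr in 1:2) {
    x[tr, 1, ] <- sin(2 * pi * 5 * t)
    x[tr, 2, ] <- rnorm(length(t))
  }
  rec <- eeg_recording(x, c("A", "B"), fs)
  out <- resample_recording(rec, 128)
  expect_identical(dim(out$data), c(2L, 2L, length(t) %/% 4L))
  expect_identical(out$channel_names, c("A", "B"))
  expect_identical(out$sampling_rate, 128)
  # FFT oracle: the 5 Hz tone stays the dominant peak after decimation
  expect_equal(peak_frequency(out$data[1, 1, ], 128), 5, tolerance = 0.1)
  # identity at the current rate
  expect_identical(resample_recording(rec, fs), rec)
  expect_error(resample_recording(rec, 1024), "upsampling")
  expect_error(resample_recording(rec, 100), "divide")
})

test_that("rating binarization follows the 4.5 threshold and is monotone", {
  r <- data.frame(subject = "s01", trial = 1:4,
                  valence = c(3.0, 7.2, 4.5, 9),
                  arousal = c(1, 4.4999, 4.5001, 5))
  expect_identical(binarize_ratings(r, "valence")$label, c(0L, 1L, 1L, 1L))
  expect_identical(binarize_ratings(r, "arousal")$label, c(0L, 0L, 1L, 1L))
  expect_identical(attr(binarize_ratings(r, "valence"), "emotion"), "valence")
  # all-high ratings give the degenerate all-ones vector
  r9 <- data.frame(subject = "s", trial = 1:3, valence = c(9, 9, 9),
                   arousal = c(9, 9, 9))
  expect_identical(binarize_ratings(r9, "valence")$label, rep(1L, 3))
  expect_error(binarize_ratings(r, "dominance"))
  # monotonicity: raising any rating never flips a label to 0
  set.seed(42)
  for (i in 1:50) {
    v <- runif(6, 1, 9)
    r2 <- data.frame(subject = "s", trial = 1:6, valence = v, arousal = v)
    bump <- pmin(v + runif(6, 0, 2), 9)
    r3 <- data.frame(subject = "s", trial = 1:6, valence = bump, arousal = bump)
    expect_true(all(binarize_ratings(r3, "valence")$label >=
                    binarize_ratings(r2, "valence")$label))
  }
  expect_error(validate_ratings(data.frame(subject = 1, trial = 1,
                                           valence = 0.5, arousal = 5)),
               "valence")
})

test_that("HDF5 container round-trips bit-exactly and reports missing fields", {
  x <- array(rnorm(3 * 2 * 256), c(3, 2, 256))
  rec <- eeg_recording(x, c("AF3", "P8"), 128, "subj7", baseline_seconds = 1)
  p <- withr::local_tempfile(fileext = ".h5")
  write_eeg_h5(rec, p)
  back <- read_recording(p, "hdf5")
  expect_identical(back$data, rec$data)
  expect_identical(back$channel_names, rec$channel_names)
  expect_identical(back$sampling_rate, rec$sampling_rate)
  expect_identical(back$subject_id, rec$subject_id)
  expect_identical(back$baseline_seconds, rec$baseline_seconds)

  # container missing /fs is rejected with the field named
  p2 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(p2)
  rhdf5::h5write(x, p2, "data")
  rhdf5::h5write(c("AF3", "P8"), p2, "channel_names")
  rhdf5::h5closeAll()
  expect_error(read_eeg_h5(p2), "/fs")
})

test_that("EDF export/import recovers the signal to quantization accuracy", {
  fs <- 128
  x <- array(rnorm(3 * 2 * 2 * fs, sd = 20), c(3, 2, 2 * fs))
  rec <- eeg_recording(x, c("Cz", "P8"), fs, "edfsub")
  p <- withr::local_tempfile(fileext = ".edf")
  pt <- withr::local_tempfile(fileext = ".csv")
  write_edf(rec, p, pt)
  back <- read_recording(p, "edf", trial_table = pt)
  expect_identical(dim(back$data), dim(rec$data))
  expect_identical(back$channel_names, rec$channel_names)
  expect_identical(back$sampling_rate, fs)
  # 16-bit quantization over ~±80 uV: step well below 0.01 uV
  expect_lt(max(abs(back$data - rec$data)), 0.01)
  expect_error(read_edf(p, NULL), "trial table")
})

test_that("EDF reader rejects mixed per-signal sampling rates", {
  # hand-build a 2-signal header with different samples-per-record
  p <- withr::local_tempfile(fileext = ".edf")
  con <- file(p, "wb")
  wf <- function(x, n) writeBin(charToRaw(substr(formatC(as.character(x),
                                                          width = -n), 1, n)), con)
  wf("0", 8); wf("pat", 80); wf("rec", 80); wf("01.01.20", 8); wf("00.00.00", 8)
  wf(256 + 2 * 256, 8); wf("", 44); wf(1, 8); wf("1", 8); wf(2, 4)
  wf("A", 16); wf("B", 16); wf("", 80); wf("", 80); wf("uV", 8); wf("uV", 8)
  wf(-100, 8); wf(-100, 8); wf(100, 8); wf(100, 8)
  wf(-32768, 8); wf(-32768, 8); wf(32767, 8); wf(32767, 8)
  wf("", 80); wf("", 80); wf(64, 8); wf(128, 8); wf("", 32); wf("", 32)
  writeBin(integer(64 + 128), con, size = 2, endian = "little")
  close(con)
  tab <- data.frame(trial_id = 1, onset_s = 0, duration_s = 1)
  expect_error(read_edf(p, tab), "mixed sampling rates")
})
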
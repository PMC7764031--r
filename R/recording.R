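#' The canonical 32-channel montage
#'
#' Channel order used by the reference 32-electrode emotion dataset,
#' following the international 10-20 positioning system.
#'
#' @return character vector of 32 channel labels.
#' @export
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
    "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
    "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
    "PO4", "O2")
}

#' Construct a multi-trial EEG recording
#'
#' The in-memory model for segmented EEG data: a `trial x channel x sample`
#' array in microvolts together with channel labels, the sampling rate and
#' the length of the pre-trial baseline still attached at the start of each
#' trial.
#'
#' @param data numeric 3-d array with dimensions (trial, channel, sample).
#' @param channel_names character vector of unique channel labels, one per
#'   channel, in the array's channel order.
#' @param sampling_rate sampling rate in Hz.
#' @param subject_id subject identifier string.
#' @param baseline_seconds seconds of pre-trial baseline included at the
#'   start of each trial (default 0).
#' @return an object of class `eeg_recording`.
#' @details All trials must share one sample count, all samples must be
#'   finite, and the post-baseline trial length need not be a whole number
#'   of seconds (feature extraction later drops any trailing partial
#'   second).
#' @examples
#' x <- array(rnorm(2 * 3 * 256), c(2, 3, 256))
#' rec <- eeg_recording(x, c("Fz", "Cz", "Pz"), 128, "s01")
#' rec
#' @export
eeg_recording <- function(data, channel_names, sampling_rate, subject_id = "s01",
                          baseline_seconds = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3-d array (trial, channel, sample)")
  if (!is.character(channel_names))
    channel_names <- as.character(channel_names)
  assert_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_number(baseline_seconds, "baseline_seconds")
  if (baseline_seconds < 0) stopf("'baseline_seconds' must be non-negative")
  rec <- structure(
    list(data = data, channel_names = channel_names,
         sampling_rate = sampling_rate, subject_id = as.character(subject_id),
         baseline_seconds = baseline_seconds),
    class = "eeg_recording")
  validate_recording(rec)
}

#' Validate an EEG recording's invariants
#'
#' Checks dimensions, channel-name uniqueness, baseline consistency and
#' that every sample is finite; a non-finite sample raises an error naming
#' the offending trial and channel.
#'
#' @param rec an [eeg_recording()].
#' @return `rec`, invisibly usable, after validation.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stopf("not an eeg_recording")
  d <- dim(rec$data)
  if (length(rec$channel_names) != d[2L])
    stopf("channel_names length (%d) does not match channel dimension (%d)",
          length(rec$channel_names), d[2L])
  if (anyDuplicated(rec$channel_names))
    stopf("channel names must be unique; duplicated: %s",
          paste(unique(rec$channel_names[duplicated(rec$channel_names)]),
                collapse = ", "))
  nb <- rec$baseline_seconds * rec$sampling_rate
  if (nb > d[3L]) stopf("baseline (%g s) exceeds trial length (%g s)",
                        rec$baseline_seconds, d[3L] / rec$sampling_rate)
  bad <- which(!is.finite(rec$data))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], d)
    stopf("non-finite sample at trial %d, channel %s (and %d more)",
          idx[1L], rec$channel_names[idx[2L]], length(bad) - 1L)
  }
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_recording> subject %s: %d trials x %d channels x %d samples (%g s @ %g Hz, baseline %g s)\n",
    x$subject_id, d[1L], d[2L], d[3L], d[3L] / x$sampling_rate,
    x$sampling_rate, x$baseline_seconds))
  invisible(x)
}

#' Number of trials in a recording
#' @param rec an [eeg_recording()].
#' @return integer trial count.
#' @export
n_trials <- function(rec) dim(rec$data)[1L]

#' Remove the pre-trial baseline from every trial
#'
#' Drops the first `baseline_seconds * sampling_rate` samples of each trial
#' and marks the result as baseline-free.  Calling it on a recording whose
#' baseline is already zero returns the recording unchanged, so the
#' operation is idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return an [eeg_recording()] with `baseline_seconds = 0`.
#' @examples
#' x <- array(rnorm(1 * 2 * (63 * 16)), c(1, 2, 63 * 16))
#' rec <- eeg_recording(x, c("Cz", "Pz"), 16, baseline_seconds = 3)
#' dim(trim_baseline(rec)$data)[3]  # 60 s * 16 Hz
#' @export
trim_baseline <- function(rec) {
  validate_recording(rec)
  nb <- round(rec$baseline_seconds * rec$sampling_rate)
  if (nb == 0L) return(rec)
  if (nb >= dim(rec$data)[3L])
    stopf("baseline (%g s) is not shorter than the trial itself",
          rec$baseline_seconds)
  rec$data <- rec$data[, , -(seq_len(nb)), drop = FALSE]
  rec$baseline_seconds <- 0
  rec
}

#' Downsample a recording with anti-aliasing
#'
#' Applies a zero-phase low-pass at 0.4 x the target rate before keeping
#' every (fs/target)-th sample of each trial and channel.  Only integer
#' decimation factors are supported; requesting a rate above the current
#' one is an unsupported-input error.
#'
#' @param rec an [eeg_recording()].
#' @param target_hz target sampling rate in Hz; must divide the current
#'   rate.
#' @return the resampled [eeg_recording()]; trial count, channel count and
#'   channel order are unchanged.
#' @examples
#' x <- array(rnorm(1 * 1 * 512), c(1, 1, 512))
#' rec <- eeg_recording(x, "Cz", 512)
#' dim(resample_recording(rec, 128)$data)[3]
#' @export
resample_recording <- function(rec, target_hz) {
  validate_recording(rec)
  assert_scalar_number(target_hz, "target_hz", positive = TRUE)
  fs <- rec$sampling_rate
  if (target_hz > fs)
    stopf("upsampling (%g -> %g Hz) is not supported", fs, target_hz)
  if (target_hz == fs) return(rec)
  fac <- fs / target_hz
  if (abs(fac - round(fac)) > 1e-9)
    stopf("unsupported decimation factor %g: target rate must divide %g Hz", fac, fs)
  fac <- as.integer(round(fac))
  bf <- signal::butter(6, (0.4 * target_hz) / (fs / 2), type = "low")
  d <- dim(rec$data)
  keep <- seq(1L, d[3L], by = fac)
  out <- array(0, c(d[1L], d[2L], length(keep)))
  for (tr in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    y <- zero_phase_filter(bf$b, bf$a, rec$data[tr, ch, ])
    out[tr, ch, ] <- y[keep]
  }
  rec$data <- out
  rec$sampling_rate <- target_hz
  rec
}
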
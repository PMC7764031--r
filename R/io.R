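# File interchange: HDF5 trial container, EDF recordings, ratings CSV.
#
# HDF5 container layout:
#   /data              double  (trial, channel, sample)
#   /channel_names     string
#   /fs                scalar
#   /baseline_seconds  scalar
#   /subject_id        string (dataset; also readable as root attribute)

#' Write an EEG recording to the HDF5 trial container
#'
#' @param rec an [eeg_recording()].
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @details Samples are stored as 64-bit floats so that a write/read
#'   round-trip reproduces the data bit-exactly.
#' @export
write_eeg_h5 <- function(rec, path) {
  validate_recording(rec)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  d <- dim(rec$data)
  # chunk by trial to keep large containers readable piecewise
  rhdf5::h5createDataset(path, "data", dims = d, storage.mode = "double",
                         chunk = c(1L, d[2L], d[3L]), level = 4L)
  rhdf5::h5write(rec$data, path, "data")
  rhdf5::h5write(rec$channel_names, path, "channel_names")
  rhdf5::h5write(rec$sampling_rate, path, "fs")
  rhdf5::h5write(rec$baseline_seconds, path, "baseline_seconds")
  rhdf5::h5write(rec$subject_id, path, "subject_id")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an EEG recording from the HDF5 trial container
#'
#' @param path path to a container written by [write_eeg_h5()] (datasets
#'   `/data`, `/channel_names`, `/fs`, `/baseline_seconds` are required,
#'   `/subject_id` optional).
#' @return a validated [eeg_recording()]; channel order is preserved from
#'   the file.
#' @export
read_eeg_h5 <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  have <- rhdf5::h5ls(path)$name
  need <- c("data", "channel_names", "fs", "baseline_seconds")
  miss <- setdiff(need, have)
  if (length(miss))
    stopf("container %s is missing dataset(s): %s", path,
          paste0("/", miss, collapse = ", "))
  dat <- rhdf5::h5read(path, "data")
  chn <- as.character(rhdf5::h5read(path, "channel_names"))
  fs <- as.numeric(rhdf5::h5read(path, "fs"))
  base <- as.numeric(rhdf5::h5read(path, "baseline_seconds"))
  sid <- if ("subject_id" %in% have)
    as.character(rhdf5::h5read(path, "subject_id")) else "s01"
  rhdf5::h5closeAll()
  eeg_recording(dat, chn, fs, sid, base)
}

#' Read a recording from disk
#'
#' Dispatches on `format`: `"hdf5"` reads the package's HDF5 trial
#' container; `"edf"` reads a continuous European Data Format recording
#' and segments it into trials using a sidecar trial table.
#'
#' @param path file path.
#' @param format `"hdf5"` or `"edf"`.
#' @param trial_table for EDF input: a data frame with columns `trial_id`,
#'   `onset_s`, `duration_s`, or the path of a CSV file with that header.
#' @param ... passed to the format-specific reader.
#' @return a validated [eeg_recording()].
#' @export
read_recording <- function(path, format = c("hdf5", "edf"), trial_table = NULL, ...) {
  format <- match.arg(format)
  switch(format,
         hdf5 = read_eeg_h5(path),
         edf = read_edf(path, trial_table = trial_table, ...))
}

## ---- EDF (European Data Format) ----------------------------------------
## 16-bit integer format; one fixed-length header plus per-signal headers,
## then data records.  No EDF package ships with this environment, so a
## minimal reader/writer for uniform-rate recordings is implemented here.

edf_field <- function(con, nchars) {
  trimws(rawToChar(readBin(con, "raw", nchars)))
}

#' Read a continuous EDF recording and segment it into trials
#'
#' Supports standard EDF with one sampling rate shared by all signals;
#' mixed per-signal rates are rejected as unsupported input.  Trial
#' boundaries come from a sidecar table (`trial_id`, `onset_s`,
#' `duration_s`); all trials must share one duration.
#'
#' @param path EDF file path.
#' @param trial_table data frame or CSV path with columns `trial_id`,
#'   `onset_s`, `duration_s`.
#' @param baseline_seconds baseline length to record on the result
#'   (the onsets should point at the start of the baseline).
#' @param subject_id subject identifier; defaults to the EDF local patient
#'   identification field when present.
#' @return a validated [eeg_recording()].
#' @export
read_edf <- function(path, trial_table, baseline_seconds = 0, subject_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(trial_table))
    stopf("EDF input requires a trial table (trial_id, onset_s, duration_s)")
  if (is.character(trial_table)) {
    trial_table <- utils::read.csv(trial_table, stringsAsFactors = FALSE)
  }
  need <- c("trial_id", "onset_s", "duration_s")
  miss <- setdiff(need, names(trial_table))
  if (length(miss)) stopf("trial table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  con <- file(path, "rb")
  on.exit(close(con))
  edf_field(con, 8)                       # version
  patient <- edf_field(con, 80)
  edf_field(con, 80)                      # recording id
  edf_field(con, 8); edf_field(con, 8)    # start date, time
  edf_field(con, 8)                       # header bytes
  edf_field(con, 44)                      # reserved
  n_rec <- as.integer(edf_field(con, 8))
  rec_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  for (i in seq_len(ns)) edf_field(con, 80)   # transducer
  for (i in seq_len(ns)) edf_field(con, 8)    # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  for (i in seq_len(ns)) edf_field(con, 80)   # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(edf_field(con, 8)), 0L)
  for (i in seq_len(ns)) edf_field(con, 32)   # reserved
  if (length(unique(nsamp)) != 1L)
    stopf("unsupported EDF: signals have mixed sampling rates (%s)",
          paste(unique(nsamp), collapse = ", "))
  fs <- nsamp[1L] / rec_dur
  total <- n_rec * nsamp[1L]
  sig <- matrix(0, ns, total)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[s], size = 2, endian = "little")
      scale <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      sig[s, ((r - 1L) * nsamp[s] + 1L):(r * nsamp[s])] <-
        phys_min[s] + (raw - dig_min[s]) * scale
    }
  }
  dur <- unique(trial_table$duration_s)
  if (length(dur) != 1L) stopf("all trials must share one duration")
  n_per <- round(dur * fs)
  nt <- nrow(trial_table)
  dat <- array(0, c(nt, ns, n_per))
  for (i in seq_len(nt)) {
    from <- round(trial_table$onset_s[i] * fs) + 1L
    to <- from + n_per - 1L
    if (to > total)
      stopf("trial %s (%g s + %g s) runs past the end of the recording",
            trial_table$trial_id[i], trial_table$onset_s[i], dur)
    dat[i, , ] <- sig[, from:to]
  }
  eeg_recording(dat, labels, fs,
                subject_id %||% (if (nzchar(patient)) patient else "s01"),
                baseline_seconds)
}

#' Write a recording as a continuous EDF file plus trial table
#'
#' Trials are concatenated back-to-back into one continuous EDF recording
#' (16-bit samples, one-second data records) and the trial boundaries are
#' returned as a sidecar table.  Quantization to the 16-bit grid means the
#' EDF round trip is close but not bit-exact, unlike the HDF5 container.
#'
#' @param rec an [eeg_recording()]; post-baseline trial length must give a
#'   whole number of samples per one-second record.
#' @param path output EDF path.
#' @param table_path optional CSV path for the trial table.
#' @return the trial table data frame, invisibly.
#' @export
write_edf <- function(rec, path, table_path = NULL) {
  validate_recording(rec)
  d <- dim(rec$data)
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer requires an integer sampling rate")
  if (d[3L] %% fs != 0) stopf("EDF writer requires whole-second trials")
  ns <- d[2L]
  sig <- matrix(aperm(rec$data, c(3L, 1L, 2L)), nrow = d[1L] * d[3L], ncol = ns)
  # per-signal physical range with headroom
  pmin <- apply(sig, 2, min); pmax <- apply(sig, 2, max)
  pad <- pmax(1e-6, (pmax - pmin) * 0.01)
  pmin <- pmin - pad; pmax <- pmax + pad
  n_rec <- nrow(sig) / fs
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, n) {
    s <- formatC(as.character(x), width = -n)
    writeBin(charToRaw(substr(s, 1, n)), con)
  }
  wf("0", 8); wf(rec$subject_id, 80); wf("eegrca export", 80)
  wf("01.01.20", 8); wf("00.00.00", 8)
  wf(256 + ns * 256, 8); wf("", 44); wf(n_rec, 8); wf("1", 8); wf(ns, 4)
  for (i in seq_len(ns)) wf(rec$channel_names[i], 16)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf("uV", 8)
  for (i in seq_len(ns)) wf(formatC(pmin[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wf(formatC(pmax[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wf(-32768, 8)
  for (i in seq_len(ns)) wf(32767, 8)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf(fs, 8)
  for (i in seq_len(ns)) wf("", 32)
  # re-read the header's physical ranges (as truncated to 8 chars) so the
  # digital scaling matches what a reader will see
  pmin_h <- as.numeric(substr(formatC(pmin, format = "g", digits = 6), 1, 8))
  pmax_h <- as.numeric(substr(formatC(pmax, format = "g", digits = 6), 1, 8))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      scale <- (pmax_h[s] - pmin_h[s]) / 65535
      dig <- round((sig[rows, s] - pmin_h[s]) / scale) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  trial_s <- d[3L] / fs
  tab <- data.frame(trial_id = seq_len(d[1L]),
                    onset_s = (seq_len(d[1L]) - 1L) * trial_s,
                    duration_s = trial_s)
  if (!is.null(table_path)) utils::write.csv(tab, table_path, row.names = FALSE)
  invisible(tab)
}

## ---- ratings ------------------------------------------------------------

#' Read a per-trial emotion ratings table
#'
#' @param path CSV file with header `subject,trial,valence,arousal`;
#'   ratings are continuous values on the 1-9 self-assessment scale.
#' @return a validated ratings data frame.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  validate_ratings(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a ratings table
#'
#' @param ratings data frame with columns `subject`, `trial`, `valence`,
#'   `arousal`; ratings must lie in \[1, 9\] and (subject, trial) pairs must
#'   be unique.
#' @return the ratings data frame.
#' @export
validate_ratings <- function(ratings) {
  need <- c("subject", "trial", "valence", "arousal")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) stopf("ratings table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  for (emo in c("valence", "arousal")) {
    v <- ratings[[emo]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 1 | v > 9))
      stopf("'%s' ratings must be finite numbers in [1, 9]", emo)
  }
  if (anyDuplicated(ratings[c("subject", "trial")]))
    stopf("duplicate (subject, trial) rows in ratings table")
  ratings
}

#' Binarize continuous ratings into low/high labels
#'
#' Ratings below the threshold map to 0 (low), ratings at or above it map
#' to 1 (high).  The scale midpoint convention puts a rating of exactly
#' 4.5 in the high class; this boundary rule is a declared design choice
#' (the low/high prose definitions cover only strict inequalities) and is
#' monotone: raising a rating never flips a label from 1 to 0.
#'
#' @param ratings a ratings data frame (see [validate_ratings()]).
#' @param emotion `"valence"` or `"arousal"`.
#' @param threshold decision threshold on the 1-9 scale (default 4.5).
#' @return a data frame with columns `subject`, `trial`, `label` (0/1) and
#'   attribute `emotion`.
#' @examples
#' r <- data.frame(subject = "s01", trial = 1:3,
#'                 valence = c(3, 4.5, 7.2), arousal = c(5, 2, 9))
#' binarize_ratings(r, "valence")$label
#' @export
binarize_ratings <- function(ratings, emotion = c("valence", "arousal"),
                             threshold = 4.5) {
  emotion <- match.arg(emotion)
  ratings <- validate_ratings(ratings)
  assert_scalar_number(threshold, "threshold")
  out <- data.frame(subject = ratings$subject, trial = ratings$trial,
                    label = as.integer(ratings[[emotion]] >= threshold))
  attr(out, "emotion") <- emotion
  out
}
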
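# Band decomposition and per-second features.

# forward-backward IIR filtering with odd-reflection edge padding; the
# single-pass core runs through stats::filter (C code).
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  np <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= np) stopf("signal too short (%d samples) for the filter order", n)
  xp <- c(2 * x[1L] - x[(np + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - np)])
  one_pass <- function(v) {
    u <- stats::filter(c(rep(0, length(b) - 1L), v), filter = b,
                       method = "convolution", sides = 1)
    u <- u[length(b):(length(b) + length(v) - 1L)]
    as.numeric(stats::filter(u, filter = -a[-1L], method = "recursive"))
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(np + 1L):(np + n)]
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase, squared magnitude response), with odd-reflection padding
#' at the edges.
#'
#' @param x numeric sample vector.
#' @param band a [band_definition()].
#' @param fs sampling rate in Hz; the band's upper edge must be below
#'   Nyquist.
#' @param order filter order of each pass (default 4).
#' @return filtered signal, same length as `x`.
#' @examples
#' fs <- 128
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 10 * t)
#' y <- bandpass_filter(x, band_definition("alpha", 8, 12), fs)
#' sd(y) / sd(x)  # ~1: 10 Hz is inside the alpha band
#' @export
bandpass_filter <- function(x, band, fs, order = 4) {
  if (!inherits(band, "band_definition")) stopf("'band' must be a band_definition")
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (band$high >= fs / 2)
    stopf("band '%s' upper edge %g Hz is at or above Nyquist (%g Hz)",
          band$name, band$high, fs / 2)
  bf <- signal::butter(order, c(band$low, band$high) / (fs / 2), type = "pass")
  zero_phase_filter(bf$b, bf$a, x)
}

#' Per-second summary statistic of a signal
#'
#' Splits the signal into non-overlapping one-second windows aligned to
#' its start (a trailing partial second is dropped) and summarizes each
#' window.
#'
#' @param x numeric sample vector, at least one second long.
#' @param fs sampling rate in Hz (samples per window).
#' @param stat `"band_power"` (mean of squared samples), `"mean_abs"`
#'   (mean absolute value) or `"mean_raw"` (arithmetic mean).
#' @return numeric vector with `floor(length(x) / fs)` values.
#' @examples
#' window_statistic(rep(2, 256), 128, "mean_raw")
#' @export
window_statistic <- function(x, fs, stat = c("band_power", "mean_abs", "mean_raw")) {
  stat <- match.arg(stat)
  assert_scalar_number(fs, "fs", positive = TRUE)
  fs <- as.integer(round(fs))
  nw <- length(x) %/% fs
  if (nw < 1L) stopf("signal (%d samples) is shorter than one window (%d samples)",
                     length(x), fs)
  m <- matrix(x[seq_len(nw * fs)], nrow = fs)
  switch(stat,
         band_power = colMeans(m^2),
         mean_abs = colMeans(abs(m)),
         mean_raw = colMeans(m))
}

#' Build the band-electrode feature matrix
#'
#' For every (trial, channel, band), band-pass filters the post-baseline
#' signal and computes the per-second statistic, producing one row per
#' trial-second and one column per band-electrode combination.  With the
#' 32-channel montage and the four default bands this yields 128 feature
#' columns.  Columns are ordered band-major within channel-major order and
#' named `"<channel>_<band>"`.
#'
#' @param rec an [eeg_recording()] or a list of them (one per subject);
#'   lists are pooled row-wise in the inter-user fashion.  Recordings must
#'   be baseline-trimmed first ([trim_baseline()]).
#' @param bands named list of [band_definition()]s (default
#'   [default_bands()]).
#' @param stat per-second statistic, see [window_statistic()].  Mean band
#'   power is the default: the plain mean of a zero-mean band-passed
#'   signal carries no information, so the power reading of the
#'   per-second "mean statistic" is used.
#' @param filter_order Butterworth order per pass (default 4).
#' @return an object of class `band_feature_matrix`: list with `values`
#'   (instances x features matrix with column names), `meta` (data frame
#'   `subject`, `trial`, `second`) and `stat`.
#' @examples
#' x <- array(rnorm(2 * 2 * 640), c(2, 2, 640))
#' rec <- eeg_recording(x, c("Cz", "Pz"), 128)
#' fm <- build_feature_matrix(rec)
#' dim(fm$values)  # 2 trials x 5 s = 10 rows, 2 channels x 4 bands = 8 cols
#' @export
build_feature_matrix <- function(rec, bands = default_bands(),
                                 stat = c("band_power", "mean_abs", "mean_raw"),
                                 filter_order = 4) {
  stat <- match.arg(stat)
  if (inherits(rec, "eeg_recording")) rec <- list(rec)
  if (!length(rec) || !all(vapply(rec, inherits, TRUE, "eeg_recording")))
    stopf("'rec' must be an eeg_recording or a list of them")
  fs <- unique(vapply(rec, function(r) r$sampling_rate, 0))
  if (length(fs) != 1L) stopf("all recordings must share one sampling rate")
  chn <- rec[[1L]]$channel_names
  for (r in rec) if (!identical(r$channel_names, chn))
    stopf("all recordings must share one channel montage")
  bands <- check_bands(bands, fs)
  pieces <- lapply(rec, function(r) {
    validate_recording(r)
    if (r$baseline_seconds > 0)
      stopf("recording '%s' still carries a %g s baseline; call trim_baseline() first",
            r$subject_id, r$baseline_seconds)
    d <- dim(r$data)
    secs <- d[3L] %/% fs
    if (secs < 1L) stopf("trials are shorter than one second")
    nfeat <- d[2L] * length(bands)
    vals <- matrix(NA_real_, d[1L] * secs, nfeat)
    col <- 0L
    for (ch in seq_len(d[2L])) for (b in bands) {
      bf <- signal::butter(filter_order, c(b$low, b$high) / (fs / 2), type = "pass")
      col <- col + 1L
      for (tr in seq_len(d[1L])) {
        y <- zero_phase_filter(bf$b, bf$a, r$data[tr, ch, ])
        vals[(tr - 1L) * secs + seq_len(secs), col] <-
          window_statistic(y, fs, stat)
      }
    }
    colnames(vals) <- as.vector(t(outer(chn, names(bands), paste, sep = "_")))
    list(values = vals,
         meta = data.frame(subject = r$subject_id,
                           trial = rep(seq_len(d[1L]), each = secs),
                           second = rep(seq_len(secs), d[1L])))
  })
  fm <- structure(
    list(values = do.call(rbind, lapply(pieces, `[[`, "values")),
         meta = do.call(rbind, lapply(pieces, `[[`, "meta")),
         stat = stat),
    class = "band_feature_matrix")
  rownames(fm$values) <- NULL
  rownames(fm$meta) <- NULL
  validate_feature_matrix(fm)
}

validate_feature_matrix <- function(fm) {
  if (!inherits(fm, "band_feature_matrix")) stopf("not a band_feature_matrix")
  if (!is.matrix(fm$values) || is.null(colnames(fm$values)))
    stopf("feature values must be a matrix with column names")
  if (nrow(fm$values) != nrow(fm$meta))
    stopf("meta rows (%d) do not match value rows (%d)",
          nrow(fm$meta), nrow(fm$values))
  if (any(!is.finite(fm$values))) stopf("feature matrix contains non-finite values")
  fm
}

#' @export
print.band_feature_matrix <- function(x, ...) {
  cat(sprintf("<band_feature_matrix> %d instances x %d features (%s), %d subject(s)\n",
              nrow(x$values), ncol(x$values), x$stat,
              length(unique(x$meta$subject))))
  invisible(x)
}

#' @export
dim.band_feature_matrix <- function(x) dim(x$values)

#' Feature column names of a feature matrix
#' @param fm a `band_feature_matrix`.
#' @return character vector of `"<channel>_<band>"` names.
#' @export
feature_names <- function(fm) colnames(fm$values)

#' Restrict a feature matrix to named columns
#' @param fm a `band_feature_matrix`.
#' @param features character vector of feature names to keep, in the given
#'   order.
#' @return a `band_feature_matrix` with only those columns.
#' @export
subset_features <- function(fm, features) {
  validate_feature_matrix(fm)
  miss <- setdiff(features, colnames(fm$values))
  if (length(miss)) stopf("unknown feature(s): %s", paste(miss, collapse = ", "))
  fm$values <- fm$values[, features, drop = FALSE]
  fm
}

#' Write a feature matrix to CSV
#'
#' Columns `subject`, `trial`, `second` followed by one column per
#' feature; floats are written losslessly (17 significant digits).
#'
#' @param fm a `band_feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  validate_feature_matrix(fm)
  df <- cbind(fm$meta,
              as.data.frame(apply(fm$values, 2, function(v)
                formatC(v, format = "g", digits = 17),
                simplify = FALSE), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @param stat statistic label to record on the result (the CSV does not
#'   carry it); default `"band_power"`.
#' @return a `band_feature_matrix`.
#' @export
read_feature_csv <- function(path, stat = "band_power") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("subject", "trial", "second")
  miss <- setdiff(meta_cols, names(df))
  if (length(miss)) stopf("feature CSV is missing column(s): %s",
                          paste(miss, collapse = ", "))
  vals <- as.matrix(df[setdiff(names(df), meta_cols)])
  storage.mode(vals) <- "double"
  validate_feature_matrix(structure(
    list(values = vals,
         meta = df[meta_cols],
         stat = stat),
    class = "band_feature_matrix"))
}

#' Broadcast per-trial labels to feature-matrix instances
#'
#' Each trial-second instance inherits the binary label of its (subject,
#' trial).
#'
#' @param fm a `band_feature_matrix`.
#' @param labels a label table from [binarize_ratings()] (columns
#'   `subject`, `trial`, `label`).
#' @return integer vector of 0/1 labels, one per instance.
#' @export
broadcast_labels <- function(fm, labels) {
  validate_feature_matrix(fm)
  key <- paste(fm$meta$subject, fm$meta$trial, sep = "\r")
  lkey <- paste(labels$subject, labels$trial, sep = "\r")
  idx <- match(key, lkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])[1L]
    stopf("no label for instance (subject, trial) = (%s)",
          gsub("\r", ", ", bad))
  }
  as.integer(labels$label[idx])
}
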
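#' Define an EEG frequency band
#'
#' @param name band name, one of `"theta"`, `"alpha"`, `"beta"`, `"gamma"`
#'   for the canonical analysis bands; arbitrary names are accepted for
#'   custom decompositions.
#' @param low lower passband edge in Hz.
#' @param high upper passband edge in Hz.
#' @return an object of class `band_definition` with fields `name`, `low`,
#'   `high`.
#' @details The delta band (0.5-3.5 Hz) is deliberately absent from the
#'   default decomposition: slow-wave activity is dominated by drift and
#'   ocular residue and carries little information about affective state,
#'   so analysis is restricted to theta and above.
#' @examples
#' band_definition("alpha", 8, 12)
#' @seealso [default_bands()]
#' @export
band_definition <- function(name, low, high) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("band 'name' must be a non-empty string")
  assert_scalar_number(low, "low", positive = TRUE)
  assert_scalar_number(high, "high")
  if (high <= low) stopf("band '%s': high (%g) must exceed low (%g)", name, high, low)
  structure(list(name = name, low = low, high = high), class = "band_definition")
}

#' The four canonical analysis bands
#'
#' Theta 4-7 Hz (mental relaxation), alpha 8-12 Hz (passive attention),
#' beta 13-30 Hz (alertness and active attention), gamma 31-47 Hz
#' (concentration).  All four fit below the Nyquist frequency of a 128 Hz
#' recording.
#'
#' @return a named list of [band_definition()] objects.
#' @examples
#' names(default_bands())
#' @export
default_bands <- function() {
  list(
    theta = band_definition("theta", 4, 7),
    alpha = band_definition("alpha", 8, 12),
    beta  = band_definition("beta", 13, 30),
    gamma = band_definition("gamma", 31, 47)
  )
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

# validate a list of bands against a sampling rate
check_bands <- function(bands, fs) {
  if (!length(bands)) stopf("at least one band is required")
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    names(bands) <- vapply(bands, function(b) b$name, "")
  nm <- vapply(bands, function(b) b$name, "")
  if (anyDuplicated(nm)) stopf("duplicate band names: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (b in bands) {
    if (!inherits(b, "band_definition")) stopf("bands must be band_definition objects")
    if (b$high >= fs / 2)
      stopf("band '%s' upper edge %g Hz is at or above Nyquist (%g Hz)",
            b$name, b$high, fs / 2)
  }
  bands
}
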
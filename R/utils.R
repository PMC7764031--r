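# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a per-stage seed from the run seed; keeps results reproducible while
# letting stages be re-run in isolation.  Values stay below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offs <- c(synth = 11L, shuffle = 23L, folds = 37L, null = 53L)
  if (!stage %in% names(offs)) stop("unknown seed stage: ", stage)
  (as.integer(seed) %% 20000000L) * 100L + offs[[stage]]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite number", name)
  if (positive && x <= 0) stopf("'%s' must be positive", name)
  invisible(x)
}
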
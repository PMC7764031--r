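# Reversed-correlation greedy selection and fixed literature channel sets.

#' Pairwise feature correlation matrix
#'
#' Absolute Pearson correlation between all feature columns.  Redundancy
#' is a magnitude notion -- a perfectly anti-correlated feature is fully
#' redundant -- so the absolute value is the default convention; signed
#' Pearson is available for sensitivity analysis.
#'
#' @param fm a `band_feature_matrix` or a plain numeric matrix with column
#'   names.
#' @param method `"absolute"` (default) or `"signed"`.
#' @return symmetric matrix of coefficients with unit diagonal.
#' @details Zero-variance columns make Pearson undefined; they raise an
#'   error listing the offending columns.  Remove them first with
#'   [drop_constant()].
#' @export
correlation_matrix <- function(fm, method = c("absolute", "signed")) {
  method <- match.arg(method)
  X <- feature_values(fm)
  if (nrow(X) < 2L) stopf("at least 2 instances are required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance column(s): %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  C <- stats::cor(X)
  if (method == "absolute") C <- abs(C)
  diag(C) <- 1
  C
}

# accept either the S3 container or a bare matrix
feature_values <- function(fm) {
  if (inherits(fm, "band_feature_matrix")) return(fm$values)
  if (is.matrix(fm)) {
    if (is.null(colnames(fm)))
      colnames(fm) <- paste0("f", seq_len(ncol(fm)))
    storage.mode(fm) <- "double"
    return(fm)
  }
  stopf("expected a band_feature_matrix or a numeric matrix")
}

#' Drop zero-variance feature columns
#'
#' @param fm a `band_feature_matrix` or numeric matrix.
#' @return list with `matrix` (same type as the input, constant columns
#'   removed) and `dropped` (character vector of removed column names).
#' @export
drop_constant <- function(fm) {
  X <- feature_values(fm)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) == ncol(X)) stopf("all columns are constant")
  keep <- colnames(X)[sds > 0]
  out <- if (inherits(fm, "band_feature_matrix")) subset_features(fm, keep)
         else X[, keep, drop = FALSE]
  list(matrix = out, dropped = dropped)
}

#' Reversed-correlation greedy feature selection
#'
#' Unsupervised selection of the `n` least mutually correlated
#' band-electrode features.  The first feature chosen is the one with the
#' lowest average correlation to all other features; each subsequent step
#' adds, among the remaining features, the one with the lowest mean
#' correlation to the already-selected set.  Class labels are never
#' consulted.
#'
#' @param fm a `band_feature_matrix` or numeric matrix with column names.
#' @param n number of features to select (1 <= n <= number of
#'   non-constant columns).
#' @param method correlation convention, see [correlation_matrix()].
#' @param drop_constant if `TRUE` (default) zero-variance columns are
#'   removed before selection and reported in the result.
#' @return an object of class `rca_selection`: list with `selected`
#'   (ordered feature names), `scores` (the winning criterion value at
#'   each step, mean correlation to the reference set), `n_requested`,
#'   `method` and `dropped_constant`.
#' @details Ties in the criterion (within 1e-12) are broken toward the
#'   lower column index in the input ordering, making the selection
#'   deterministic.
#' @examples
#' set.seed(1)
#' X <- cbind(a = rnorm(100), b = rnorm(100))
#' X <- cbind(X, a2 = X[, "a"] + rnorm(100, sd = 0.05))
#' rca_select(X, 2)$selected  # picks b plus one of the a-clones
#' @export
rca_select <- function(fm, n, method = c("absolute", "signed"),
                       drop_constant = TRUE) {
  method <- match.arg(method)
  X <- feature_values(fm)
  dropped <- character(0)
  if (drop_constant) {
    dc <- drop_constant(X)
    X <- feature_values(dc$matrix)
    dropped <- dc$dropped
  }
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 1)
    stopf("'n' must be a positive integer")
  n <- as.integer(n)
  if (n > ncol(X))
    stopf("n = %d exceeds the %d available non-constant columns", n, ncol(X))
  C <- correlation_matrix(X, method = method)
  diag(C) <- 0
  p <- ncol(C)
  sel <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(n)) {
    crit <- if (step == 1L) {
      if (p == 1L) 0 else rowSums(C) / (p - 1)
    } else {
      rowMeans(C[, sel, drop = FALSE])
    }
    crit[sel] <- Inf
    # deterministic tie-break: lowest column index within 1e-12
    best <- which(crit <= min(crit) + 1e-12)[1L]
    sel <- c(sel, best)
    scores <- c(scores, crit[best])
  }
  structure(list(selected = colnames(C)[sel], scores = scores,
                 n_requested = n, method = method,
                 dropped_constant = dropped),
            class = "rca_selection")
}

#' @export
print.rca_selection <- function(x, ...) {
  cat(sprintf("<rca_selection> %d feature(s) [%s correlation]\n",
              length(x$selected), x$method))
  for (i in seq_along(x$selected))
    cat(sprintf("  %d. %-12s (criterion %.4f)\n", i, x$selected[i], x$scores[i]))
  if (length(x$dropped_constant))
    cat("  dropped constant:", paste(x$dropped_constant, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection result as JSON
#'
#' @param sel an `rca_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(sel, path) {
  jsonlite::write_json(
    list(n = sel$n_requested, selected = sel$selected,
         scores = sel$scores, method = sel$method,
         dropped_constant = sel$dropped_constant),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## ---- fixed literature channel sets -------------------------------------

fixed_set_table <- function() {
  list(
    CHS1 = list(source = "Koelstra et al.", emotions = "valence",
                features = c("PO4_theta", "FC6_beta", "Cz_beta")),
    CHS2 = list(source = "Koelstra et al.", emotions = "arousal",
                features = c("CP6_theta", "Cz_alpha", "FC2_beta")),
    CHS3 = list(source = "Koelstra et al.", emotions = "valence",
                features = c("FC2_beta", "FC6_beta", "Cz_beta")),
    CHS4 = list(source = "Soroush et al.", emotions = "arousal",
                features = c("PO4_beta", "FC1_beta", "FC6_beta")),
    CHS5 = list(source = "Soroush et al.", emotions = "valence",
                features = c("FC6_beta", "P4_theta", "PO4_theta")),
    CHS6 = list(source = "Frantzidis et al.", emotions = c("valence", "arousal"),
                features = c("Cz_beta", "Fz_beta", "Pz_beta")),
    CHS7 = list(source = "Frantzidis et al.", emotions = c("valence", "arousal"),
                features = c("Cz_theta", "Fz_theta", "Pz_theta"))
  )
}

#' Fixed three-feature channel sets from the emotion literature
#'
#' Benchmark band-electrode triples proposed in earlier studies: CHS1-CHS3
#' (Koelstra et al.), CHS4-CHS5 (Soroush et al.) and the central-electrode
#' sets CHS6-CHS7 (Frantzidis et al.).  Some sets were derived for a
#' single emotion and are marked applicable to that emotion only.
#'
#' @param id set identifier, `"CHS1"` .. `"CHS7"` (case-insensitive).
#' @return an object of class `fixed_channel_set`: list with `id`,
#'   `source`, `emotions` (applicable emotions) and `features` (three
#'   `"<channel>_<band>"` names).
#' @examples
#' get_fixed_set("CHS7")$features
#' @export
get_fixed_set <- function(id) {
  tab <- fixed_set_table()
  key <- toupper(as.character(id)[1L])
  if (!key %in% names(tab))
    stopf("unknown channel set '%s' (known: %s)", id,
          paste(names(tab), collapse = ", "))
  entry <- tab[[key]]
  structure(c(list(id = key), entry), class = "fixed_channel_set")
}

#' All fixed literature channel-set identifiers
#' @return character vector `"CHS1"` .. `"CHS7"`.
#' @export
fixed_set_ids <- function() names(fixed_set_table())

#' @export
print.fixed_channel_set <- function(x, ...) {
  cat(sprintf("<fixed_channel_set> %s (%s; %s): %s\n", x$id, x$source,
              paste(x$emotions, collapse = "/"),
              paste(x$features, collapse = ", ")))
  invisible(x)
}
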
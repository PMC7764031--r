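# SVM evaluation of channel selections under stratified k-fold
# cross-validation with in-fold feature selection.

#' Selector specifications for [crossval_pipeline()]
#'
#' `selector_none()` keeps all features; `selector_rca(n)` runs the
#' reversed-correlation selection on each training fold;
#' `selector_fixed(x)` restricts to a fixed feature set given as a
#' `"CHS1"`..`"CHS7"` identifier, a [get_fixed_set()] object or a
#' character vector of feature names.
#'
#' @param n number of features for the greedy selection.
#' @param method correlation convention, see [correlation_matrix()].
#' @param x fixed set identifier, object or feature names.
#' @return an object of class `eeg_selector`.
#' @name selectors
NULL

#' @rdname selectors
#' @export
selector_none <- function() {
  structure(list(type = "none", id = "none"), class = "eeg_selector")
}

#' @rdname selectors
#' @export
selector_rca <- function(n = 3, method = "absolute") {
  structure(list(type = "rca", n = n, method = method,
                 id = sprintf("rca:%d", as.integer(n))),
            class = "eeg_selector")
}

#' @rdname selectors
#' @export
selector_fixed <- function(x) {
  if (inherits(x, "fixed_channel_set")) {
    set <- x
  } else if (is.character(x) && length(x) == 1L &&
             toupper(x) %in% fixed_set_ids()) {
    set <- get_fixed_set(x)
  } else if (is.character(x)) {
    set <- structure(list(id = "custom", source = "user",
                          emotions = c("valence", "arousal"), features = x),
                     class = "fixed_channel_set")
  } else stopf("cannot interpret fixed selector specification")
  structure(list(type = "fixed", set = set, id = set$id),
            class = "eeg_selector")
}

# stratified fold assignment: a pure function of (labels-in-shuffled-order,
# k); each fold receives both classes as evenly as possible.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated SVM evaluation of a channel selection
#'
#' Shuffles the pooled instances with the given seed, splits them into
#' `k` stratified folds, and for every fold: fits the selector on the
#' training instances only (for the greedy selector), restricts both
#' partitions to the selected features, standardizes columns by
#' training-fold mean and standard deviation, trains a Gaussian-RBF
#' support vector machine, and scores accuracy on the held-out fold.
#'
#' @param fm a `band_feature_matrix` (or numeric matrix with column
#'   names).
#' @param labels a per-trial label table from [binarize_ratings()], or an
#'   integer 0/1 vector with one entry per instance.
#' @param selector an `eeg_selector` (default [selector_none()]).
#' @param k number of folds (default 10).
#' @param seed integer seed governing the instance shuffle (and thereby
#'   the fold partition, which is a function of instance count, labels,
#'   `k` and `seed` only).
#' @param cost SVM soft-margin constant C (default 1).
#' @param gamma RBF kernel width; default `1 / n_features`, the standard
#'   inverse-dimension heuristic on standardized features.
#' @return an object of class `cv_report`: `emotion`, `channel_set_id`,
#'   `fold_accuracies`, `mean_accuracy`, `std_accuracy`, `k`, `seed`,
#'   `selected` (features chosen on the full matrix, for reference),
#'   `fold_selected` (per-fold selections) and `fold_of_instance` (fold id
#'   of every input row, in input order).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(100 * 2), ncol = 2),
#'            matrix(rnorm(100 * 2, mean = 4), ncol = 2))
#' colnames(X) <- c("f1", "f2")
#' y <- rep(0:1, each = 100)
#' crossval_pipeline(X, y, k = 5, seed = 1)$mean_accuracy
#' @export
crossval_pipeline <- function(fm, labels, selector = selector_none(), k = 10,
                              seed = 1, cost = 1, gamma = NULL) {
  X <- feature_values(fm)
  emotion <- NULL
  if (is.data.frame(labels)) {
    emotion <- attr(labels, "emotion")
    y <- broadcast_labels(fm, labels)
  } else {
    y <- as.integer(labels)
    if (length(y) != nrow(X))
      stopf("labels length (%d) does not match instance count (%d)",
            length(y), nrow(X))
  }
  if (length(unique(y)) < 2L) stopf("labels contain a single class")
  if (!is.numeric(k) || k < 2) stopf("k must be at least 2")
  k <- as.integer(k)
  if (k > nrow(X)) stopf("k = %d exceeds the %d instances", k, nrow(X))
  if (!inherits(selector, "eeg_selector")) stopf("'selector' must be an eeg_selector")

  ord <- with_seed(derive_seed(seed, "shuffle"), sample.int(nrow(X)))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  folds <- stratified_folds(y, k)

  pick_features <- function(train_idx) {
    switch(selector$type,
           none = colnames(X),
           rca = rca_select(X[train_idx, , drop = FALSE], selector$n,
                            method = selector$method)$selected,
           fixed = {
             miss <- setdiff(selector$set$features, colnames(X))
             if (length(miss))
               stopf("fixed set %s names feature(s) absent from the matrix: %s",
                     selector$id, paste(miss, collapse = ", "))
             selector$set$features
           })
  }

  acc <- numeric(k)
  fold_selected <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    feats <- pick_features(tr)
    fold_selected[[f]] <- feats
    Xtr <- X[tr, feats, drop = FALSE]
    Xte <- X[te, feats, drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- scale(Xtr, center = mu, scale = sdv)
    Xte <- scale(Xte, center = mu, scale = sdv)
    fit <- e1071::svm(Xtr, factor(y[tr], levels = sort(unique(y))),
                      kernel = "radial", cost = cost,
                      gamma = gamma %||% (1 / ncol(Xtr)), scale = FALSE)
    acc[f] <- mean(as.character(stats::predict(fit, Xte)) == as.character(y[te]))
  }
  structure(list(
    emotion = emotion,
    channel_set_id = selector$id,
    fold_accuracies = acc,
    mean_accuracy = mean(acc),
    std_accuracy = stats::sd(acc),
    k = k, seed = seed,
    selected = pick_features(seq_len(nrow(X))),
    fold_selected = fold_selected,
    fold_of_instance = folds[order(ord)]),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s%s: accuracy %.4f +/- %.4f (%d-fold, seed %d)\n",
              x$channel_set_id,
              if (is.null(x$emotion)) "" else paste0(" [", x$emotion, "]"),
              x$mean_accuracy, x$std_accuracy, x$k, x$seed))
  invisible(x)
}

# Welch two-sided t-test on fold accuracies, with the degenerate
# both-constant case defined explicitly (identical constants: p = 1,
# different constants: p = 0).
welch_p <- function(a, b, paired = FALSE) {
  if (paired) {
    d <- a - b
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    return(stats::t.test(d)$p.value)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Compare channel-set evaluations against a reference
#'
#' Builds the comparison table: per channel set, its mean accuracy, the
#' reference's gain over it in percentage points (positive = reference
#' better) and a two-sided Welch t-test p-value on the fold accuracies,
#' flagged significant at alpha = 0.05.  All reports must share emotion,
#' `k` and fold-partition seed.
#'
#' @param reference the reference `cv_report` (typically the greedy
#'   selection).
#' @param others list of `cv_report`s to compare against.
#' @param test `"welch"` (default) or `"paired"` (paired t-test over
#'   folds).
#' @param alpha significance level (default 0.05).
#' @return an object of class `comparison_report`: `reference_id`,
#'   `emotion`, `rows` (data frame `id`, `mean_accuracy`, `gain_pp`,
#'   `p_value`, `significant`, `applicable`).
#' @export
compare_sets <- function(reference, others, test = c("welch", "paired"),
                         alpha = 0.05) {
  test <- match.arg(test)
  if (!inherits(reference, "cv_report")) stopf("'reference' must be a cv_report")
  if (inherits(others, "cv_report")) others <- list(others)
  rows <- lapply(others, function(r) {
    if (is.null(r)) return(NULL)
    if (!inherits(r, "cv_report")) stopf("'others' must contain cv_reports")
    if (!identical(r$k, reference$k))
      stopf("mismatched k between reports (%d vs %d)", r$k, reference$k)
    if (!identical(r$seed, reference$seed))
      stopf("mismatched fold seed between reports")
    if (!identical(r$emotion, reference$emotion))
      stopf("mismatched emotion between reports ('%s' vs '%s')",
            r$emotion %||% "?", reference$emotion %||% "?")
    p <- welch_p(reference$fold_accuracies, r$fold_accuracies,
                 paired = (test == "paired"))
    data.frame(id = r$channel_set_id,
               mean_accuracy = r$mean_accuracy,
               gain_pp = 100 * (reference$mean_accuracy - r$mean_accuracy),
               p_value = p,
               significant = p <= alpha,
               applicable = TRUE)
  })
  structure(list(reference_id = reference$channel_set_id,
                 reference_accuracy = reference$mean_accuracy,
                 emotion = reference$emotion,
                 test = test, alpha = alpha,
                 rows = do.call(rbind, rows)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> reference %s%s: accuracy %.4f\n",
              x$reference_id,
              if (is.null(x$emotion)) "" else paste0(" [", x$emotion, "]"),
              x$reference_accuracy))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Run the full channel-set comparison experiment
#'
#' For each requested emotion, evaluates the all-features baseline, the
#' greedy selection (the reference) and every requested fixed literature
#' set, all under one shared fold partition, and assembles one comparison
#' report per emotion.  Fixed sets whose source study addressed only the
#' other emotion are kept in the table but marked not applicable, with
#' blank metrics.
#'
#' @param fm a `band_feature_matrix`.
#' @param ratings a ratings table (see [validate_ratings()]).
#' @param emotions character vector among `"valence"`, `"arousal"`.
#' @param sets channel sets to evaluate: `"none"` and/or `"CHS1"`..`"CHS7"`.
#' @param n features selected by the greedy reference (default 3).
#' @param k folds (default 10).
#' @param seed integer seed shared by every evaluation.
#' @param ... passed to [crossval_pipeline()] (e.g. `cost`).
#' @return named list (one entry per emotion) of `comparison_report`s,
#'   each carrying the underlying `cv_report`s in `$reports`.
#' @export
run_comparison_experiment <- function(fm, ratings,
                                      emotions = c("valence", "arousal"),
                                      sets = c("none", fixed_set_ids()),
                                      n = 3, k = 10, seed = 1, ...) {
  emotions <- match.arg(emotions, several.ok = TRUE)
  out <- list()
  for (emo in emotions) {
    labels <- binarize_ratings(ratings, emo)
    ref <- crossval_pipeline(fm, labels, selector_rca(n), k = k, seed = seed, ...)
    reports <- list()
    na_rows <- list()
    for (s in sets) {
      if (identical(tolower(s), "none")) {
        reports[[s]] <- crossval_pipeline(fm, labels, selector_none(),
                                          k = k, seed = seed, ...)
      } else {
        fset <- get_fixed_set(s)
        if (!emo %in% fset$emotions) {
          na_rows[[s]] <- data.frame(id = fset$id, mean_accuracy = NA_real_,
                                     gain_pp = NA_real_, p_value = NA_real_,
                                     significant = NA, applicable = FALSE)
        } else {
          reports[[s]] <- crossval_pipeline(fm, labels, selector_fixed(fset),
                                            k = k, seed = seed, ...)
        }
      }
    }
    cmp <- compare_sets(ref, reports)
    if (length(na_rows)) {
      cmp$rows <- rbind(cmp$rows, do.call(rbind, na_rows))
      # keep requested order
      ids <- vapply(sets, function(s)
        if (identical(tolower(s), "none")) "none" else toupper(s), "")
      cmp$rows <- cmp$rows[match(ids, cmp$rows$id), , drop = FALSE]
      rownames(cmp$rows) <- NULL
    }
    cmp$reports <- c(list(ref), unname(reports))
    out[[emo]] <- cmp
  }
  out
}

#' Write a cross-validation report as JSON
#' @param report a `cv_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(report, path) {
  jsonlite::write_json(
    report[c("emotion", "channel_set_id", "fold_accuracies", "mean_accuracy",
             "std_accuracy", "k", "seed", "selected")],
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a comparison report as CSV
#'
#' Columns mirror the standard comparison layout: method, ACC (percent),
#' reference gain (percentage points) and p-value; not-applicable rows
#' keep blank metrics.
#'
#' @param cmp a `comparison_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(cmp, path) {
  ref_row <- data.frame(method = cmp$reference_id,
                        acc_percent = 100 * cmp$reference_accuracy,
                        gain_pp = NA_real_, p_value = NA_real_)
  rows <- data.frame(method = cmp$rows$id,
                     acc_percent = 100 * cmp$rows$mean_accuracy,
                     gain_pp = cmp$rows$gain_pp,
                     p_value = cmp$rows$p_value)
  utils::write.csv(rbind(ref_row, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
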
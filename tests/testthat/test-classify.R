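# SVM cross-validation, comparison statistics and the experiment driver.

make_blobs <- function(n_per, sep, seed, p = 2) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), ncol = p),
             matrix(rnorm(n_per * p, mean = sep), ncol = p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(0:1, each = n_per))
}

test_that("well-separated classes are classified nearly perfectly", {
  d <- make_blobs(300, 10, seed = 21)
  rep <- crossval_pipeline(d$X, d$y, selector_none(), k = 10, seed = 1)
  expect_gte(rep$mean_accuracy, 0.99)
  expect_length(rep$fold_accuracies, 10)
  expect_true(all(rep$fold_accuracies >= 0 & rep$fold_accuracies <= 1))
  expect_equal(rep$mean_accuracy, mean(rep$fold_accuracies))
  expect_equal(rep$std_accuracy, sd(rep$fold_accuracies))
})

test_that("permuted labels score at chance level", {
  d <- make_blobs(600, 10, seed = 22)
  set.seed(97)
  y_null <- sample(d$y)
  rep <- crossval_pipeline(d$X, y_null, selector_none(), k = 10, seed = 3)
  expect_gt(rep$mean_accuracy, 0.45)
  expect_lt(rep$mean_accuracy, 0.55)
})

test_that("cross-validation input contracts are enforced", {
  d <- make_blobs(20, 5, seed = 23)
  expect_error(crossval_pipeline(d$X, rep(1L, 40), k = 5), "single class")
  expect_error(crossval_pipeline(d$X, d$y, k = 1), "at least 2")
  expect_error(crossval_pipeline(d$X, d$y, k = 41), "exceeds")
  expect_error(crossval_pipeline(d$X, d$y[-1], k = 5), "labels length")
})

test_that("fold partition depends only on the seed and is shared across selectors", {
  d <- make_blobs(100, 3, seed = 24, p = 4)
  r1 <- crossval_pipeline(d$X, d$y, selector_none(), k = 5, seed = 11)
  r2 <- crossval_pipeline(d$X, d$y, selector_rca(2), k = 5, seed = 11)
  r3 <- crossval_pipeline(d$X, d$y, selector_none(), k = 5, seed = 12)
  expect_identical(r1$fold_of_instance, r2$fold_of_instance)
  expect_false(identical(r1$fold_of_instance, r3$fold_of_instance))
  # stratification: both classes in every fold
  tab <- table(r1$fold_of_instance, d$y)
  expect_true(all(tab > 0))
})

test_that("greedy selection sees only the training folds (no information leak)", {
  set.seed(25)
  n <- 200
  f <- rnorm(n)
  X <- cbind(c1 = f + rnorm(n, sd = 0.1), c2 = f + rnorm(n, sd = 0.1),
             ind = rnorm(n), c3 = f + rnorm(n, sd = 0.1))
  y <- rep(0:1, n / 2)
  r1 <- crossval_pipeline(X, y, selector_rca(1), k = 4, seed = 5)
  # replace each fold's held-out rows with fresh noise: training-side
  # selections must not move
  for (f_id in 1:4) {
    X2 <- X
    rows <- which(r1$fold_of_instance == f_id)
    set.seed(1000 + f_id)
    X2[rows, ] <- matrix(rnorm(length(rows) * ncol(X)), length(rows))
    r2 <- crossval_pipeline(X2, y, selector_rca(1), k = 4, seed = 5)
    expect_identical(r2$fold_selected[[f_id]], r1$fold_selected[[f_id]])
  }
})

test_that("accuracy is invariant under per-column affine rescaling", {
  d <- make_blobs(150, 2, seed = 26, p = 3)
  r1 <- crossval_pipeline(d$X, d$y, selector_none(), k = 5, seed = 7)
  Xs <- sweep(sweep(d$X, 2, c(100, 0.01, 3), "*"), 2, c(-5, 40, 0), "+")
  r2 <- crossval_pipeline(Xs, d$y, selector_none(), k = 5, seed = 7)
  expect_equal(r1$fold_accuracies, r2$fold_accuracies, tolerance = 1e-10)
})

test_that("comparison statistics match the textbook Welch formula", {
  set.seed(27)
  mk <- function(acc) {
    structure(list(emotion = "valence", channel_set_id = "x",
                   fold_accuracies = acc, mean_accuracy = mean(acc),
                   std_accuracy = sd(acc), k = length(acc), seed = 1L),
              class = "cv_report")
  }
  a <- pmin(pmax(rnorm(10, 0.7, 0.05), 0), 1)
  b <- pmin(pmax(rnorm(10, 0.65, 0.08), 0), 1)
  ra <- mk(a); ra$channel_set_id <- "ref"
  rb <- mk(b)
  cmp <- compare_sets(ra, rb)
  expect_equal(cmp$rows$p_value, welch_brute(a, b), tolerance = 1e-12)
  expect_equal(cmp$rows$gain_pp, 100 * (mean(a) - mean(b)))

  # self-comparison: zero gain, p = 1
  cmp_self <- compare_sets(ra, mk(a))
  expect_equal(cmp_self$rows$gain_pp, 0)
  expect_equal(cmp_self$rows$p_value, 1)

  # degenerate zero-variance folds: treated as a significant difference
  hi <- mk(rep(0.9, 10)); hi$channel_set_id <- "ref"
  lo <- mk(rep(0.5, 10))
  cmp_deg <- compare_sets(hi, lo)
  expect_equal(cmp_deg$rows$gain_pp, 40)
  expect_lt(cmp_deg$rows$p_value, 0.05)
  expect_true(cmp_deg$rows$significant)

  # mismatched protocol is rejected
  bad_k <- mk(a[1:5])
  expect_error(compare_sets(ra, bad_k), "mismatched k")
  bad_emo <- mk(b); bad_emo$emotion <- "arousal"
  expect_error(compare_sets(ra, bad_emo), "emotion")
})

test_that("the comparison experiment reports every requested set per emotion", {
  gen <- synth_generate(synth_config(n_subjects = 1, n_trials_per_subject = 8,
                                     trial_seconds = 10, baseline_seconds = 1,
                                     seed = 31))
  fm <- build_feature_matrix(trim_baseline(gen$recordings[[1]]))
  res <- run_comparison_experiment(fm, gen$ratings,
                                   sets = c("none", "CHS1", "CHS6", "CHS7"),
                                   n = 3, k = 4, seed = 2)
  expect_named(res, c("valence", "arousal"))
  for (emo in names(res)) {
    expect_identical(nrow(res[[emo]]$rows), 4L)
    expect_identical(res[[emo]]$reference_id, "rca:3")
  }
  # CHS1 was proposed for valence only: the arousal row stays blank
  chs1_arousal <- res$arousal$rows[res$arousal$rows$id == "CHS1", ]
  expect_false(chs1_arousal$applicable)
  expect_true(is.na(chs1_arousal$mean_accuracy))
  chs1_valence <- res$valence$rows[res$valence$rows$id == "CHS1", ]
  expect_true(chs1_valence$applicable)

  # determinism: the identical call reproduces identical numbers
  res2 <- run_comparison_experiment(fm, gen$ratings,
                                    sets = c("none", "CHS1", "CHS6", "CHS7"),
                                    n = 3, k = 4, seed = 2)
  expect_identical(res2$valence$rows, res$valence$rows)
  expect_identical(res2$arousal$rows, res$arousal$rows)

  # report writers produce the documented layouts
  pj <- withr::local_tempfile(fileext = ".json")
  write_cv_json(res$valence$reports[[1]], pj)
  back <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_identical(back$channel_set_id, "rca:3")
  expect_length(back$fold_accuracies, 4)
  pc <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(res$valence, pc)
  tab <- read.csv(pc)
  expect_identical(names(tab), c("method", "acc_percent", "gain_pp", "p_value"))
  expect_identical(tab$method[1], "rca:3")
})
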
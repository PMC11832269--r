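test_that("metric arithmetic matches the contingency table", {
  y_true <- c(rep(1, 4), rep(0, 6))
  y_pred <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)  # TP 3, FN 1, FP 1, TN 5
  scores <- y_pred
  m <- compute_metrics(y_true, y_pred, scores)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$fscore, 0.75)
})

test_that("AUROC is the rank statistic and agrees with pROC", {
  y <- c(rep(0, 5), rep(1, 5))
  expect_equal(compute_metrics(y, y, seq(0.1, 1, 0.1))$auroc, 1.0)
  set.seed(8)
  y2 <- rbinom(200, 1, 0.3)
  s2 <- rnorm(200) + y2
  ours <- compute_metrics(y2, as.integer(s2 > 0.5), s2)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("zero-division guards and input checks behave", {
  y <- c(0, 0, 1, 1)
  expect_warning(m <- compute_metrics(y, c(0, 0, 0, 0), c(0.1, 0.2, 0.3, 0.4)),
                 "no positive predictions")
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$fscore, 0)
  expect_error(compute_metrics(y, c(0, 1), c(0.5, 0.5)), "equal length")
  # single-class truth: AUROC undefined
  expect_true(is.na(suppressWarnings(
    compute_metrics(c(1, 1), c(1, 1), c(0.9, 0.8))$auroc)))
})

blobs <- function(n = 60, sep = 6, seed = 9) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4) + sep * y
  list(X = X, y = y)
}

test_that("every classifier separates well-separated blobs and is deterministic", {
  b <- blobs()
  holdout <- blobs(seed = 10)
  for (name in c("GB", "SVM", "KNN", "LR", "MLP")) {
    spec <- classifier_spec(name, seed = 3)
    fit <- train_classifier(spec, b$X, b$y)
    acc <- mean(predict_classifier(fit, b$X)$pred == b$y)
    expect_gte(acc, 0.99)
    # refit with the same seed: identical held-out predictions
    fit2 <- train_classifier(spec, b$X, b$y)
    expect_identical(predict_classifier(fit, holdout$X)$pred,
                     predict_classifier(fit2, holdout$X)$pred)
  }
  expect_error(train_classifier(classifier_spec("KNN"), b$X, rep(0, 60)),
               "single class")
  expect_error(classifier_spec("KNN", k = 25), "1, 20")
})

test_that("automatic k selection prefers small k on clean clusters", {
  # noise-free clusters: 1-NN is Bayes-optimal
  set.seed(11)
  y <- rep(c(0, 1), each = 40)
  X <- matrix(rnorm(80 * 2, sd = 0.05), 80, 2) + 10 * y
  expect_equal(select_knn_k(X, y, k_max = 10), 1)
  expect_equal(select_knn_k(X, y, k_max = 1), 1)
  # on duplicated points all k tie; the smaller k must win
  Xd <- matrix(rep(c(0, 1), each = 20), ncol = 1)
  yd <- rep(c(0, 1), each = 20)
  expect_equal(select_knn_k(Xd, yd, k_max = 5, seed = 2), 1)
  expect_error(select_knn_k(X[1:3, ], y[1:3], inner_folds = 5), "inner folds")
})

test_that("cross-validation aggregates folds consistently", {
  segs <- fx_signal16()
  rep_ <- crossval_evaluate(segs, fx_knn(),
                            make_cv_splits(segs, "stratified-k-fold", k = 5, seed = 1))
  expect_equal(nrow(rep_$per_fold), 5)
  expect_true(all(rep_$sd >= 0))
  # confusion totals equal the test size per fold
  plan <- make_cv_splits(segs, "stratified-k-fold", k = 5, seed = 1)
  for (f in 1:5) {
    expect_equal(sum(rep_$confusion[[f]]), length(plan$folds[[f]]$test))
  }
  # F-score internal consistency with the reported precision/recall
  for (f in 1:5) {
    p <- rep_$per_fold[f, "precision"]; r <- rep_$per_fold[f, "recall"]
    fs <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_equal(unname(rep_$per_fold[f, "fscore"]), unname(fs), tolerance = 1e-12)
  }
  # means sit inside the fold range
  for (m in colnames(rep_$per_fold)) {
    expect_gte(rep_$mean[[m]], min(rep_$per_fold[, m], na.rm = TRUE))
    expect_lte(rep_$mean[[m]], max(rep_$per_fold[, m], na.rm = TRUE))
  }
})

test_that("null data scores in the chance band; strong signal scores high", {
  null_rep <- crossval_evaluate(fx_null16(), fx_knn(),
                                make_cv_splits(fx_null16(), k = 5, seed = 2))
  for (m in c("accuracy", "fscore", "precision", "recall", "auroc")) {
    expect_gte(null_rep$mean[[m]], 0.35)
    expect_lte(null_rep$mean[[m]], 0.65)
  }
  sig_rep <- crossval_evaluate(fx_signal16(), fx_knn(),
                               make_cv_splits(fx_signal16(), k = 10, seed = 1))
  expect_gte(sig_rep$mean[["accuracy"]], 0.85)
  expect_gte(sig_rep$mean[["auroc"]], 0.9)
})

test_that("LOSO transfers shared effects but not subject-specific ones", {
  shared <- synth_config(n_subjects = 6, epochs_per_subject = 10, fs_raw = 100,
                         epoch_len = 10, effect_size = 3, class_prior = 0.4,
                         channel_names = c(fx_ch16(), "A1", "A2"),
                         informative_channels = 1:3, seed = 31)
  segs <- preprocess_dataset(generate_labeled_dataset(shared), 100, c(0, 35), 2)
  res <- loso_evaluate(segs, fx_knn())
  expect_equal(nrow(res$per_subject), 6)
  expect_gte(res$overall$mean[["accuracy"]], 0.65)

  # subject-specific informative sets drawn from the full 58-channel
  # montage barely overlap across subjects, so nothing should transfer
  specific <- synth_config(n_subjects = 6, epochs_per_subject = 10, fs_raw = 100,
                           epoch_len = 10, effect_size = 3, class_prior = 0.4,
                           informative_channels = 1:3,
                           subject_specific_channels = TRUE, seed = 32)
  segs2 <- preprocess_dataset(generate_labeled_dataset(specific), 100, c(0, 35), 2)
  res2 <- loso_evaluate(segs2, fx_knn())
  expect_gte(res2$overall$mean[["auroc"]], 0.4)
  expect_lte(res2$overall$mean[["auroc"]], 0.65)
})

test_that("random-label nulls expose the accuracy trap on skewed test sets", {
  segs <- fx_signal16()
  plan <- make_cv_splits(segs, k = 5, seed = 3)
  bal <- random_label_null(segs, fx_knn(), dist = c(0.5, 0.5), reps = 5,
                           cvplan = plan, seed = 1)
  expect_lt(abs(bal$mean[["auroc"]] - 0.5), 0.07)
  # predictions are mostly dreamless (23% prior), so with 90% dream test
  # labels accuracy collapses toward 0.1-0.3 while recall stays low
  skew <- random_label_null(segs, fx_knn(), dist = c(0.1, 0.9), reps = 5,
                            cvplan = plan, seed = 1)
  expect_lt(skew$mean[["accuracy"]], 0.45)
  # with 90% dreamless labels the F-score for the dream class is near zero
  skew2 <- random_label_null(segs, fx_knn(), dist = c(0.9, 0.1), reps = 5,
                             cvplan = plan, seed = 1)
  expect_lt(skew2$mean[["fscore"]], 0.3)
  expect_error(random_label_null(segs, fx_knn(), dist = c(0, 1)), "non-degenerate")
  expect_error(random_label_null(segs, fx_knn(), dist = c(0.6, 0.6)), "sum to 1")
})
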
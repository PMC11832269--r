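# End-to-end pipeline: feature extraction (CSP or DWT path) fitted on the
# training side only, followed by a classifier. The fitted pipeline never
# sees test rows.

#' Configure a feature + classifier pipeline
#'
#' @param feature `"csp"` (spatial filters, log-variance, PCA rotation,
#'   z-scoring) or `"dwt"` (wavelet feature battery, z-scoring only).
#' @param classifier A [classifier_spec()].
#' @param wavelet,levels,kmax DWT-path options.
#' @param csp_components CSP/PCA component count (default: channel count).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(feature = c("csp", "dwt"),
                            classifier = classifier_spec("KNN"),
                            wavelet = "bior2.2", levels = 4, kmax = 10,
                            csp_components = NULL) {
  feature <- match.arg(feature)
  structure(list(feature = feature, classifier = classifier,
                 wavelet = wavelet, levels = levels, kmax = kmax,
                 csp_components = csp_components),
            class = "pipeline_config")
}

# z-scoring fitted on training rows (the DWT path's postprocessor)
fit_zscore <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  list(mean = mu, sd = sd_)
}

apply_zscore <- function(z, X) {
  sweep(sweep(X, 2, z$mean), 2, z$sd, `/`)
}

raw_features <- function(config, segments, csp_model = NULL) {
  if (config$feature == "csp") {
    csp_features(csp_model, segments)
  } else {
    dwt_feature_matrix(segments, config$wavelet, config$levels, config$kmax)
  }
}

#' Fit the full pipeline on a training segment set
#'
#' @param segments Training `segment_set` (both classes present).
#' @param config A [pipeline_config()].
#' @return A `pipeline_model` usable with [predict_pipeline()].
#' @export
fit_pipeline <- function(segments, config) {
  if (!inherits(config, "pipeline_config")) stopf("'config' must be a pipeline_config")
  csp_model <- NULL
  if (config$feature == "csp") {
    csp_model <- fit_csp(segments)
  }
  feats <- raw_features(config, segments, csp_model)
  post <- if (config$feature == "csp") {
    fit_feature_postprocess(feats, config$csp_components)
  } else {
    fit_zscore(feats)
  }
  X <- if (config$feature == "csp") {
    apply_feature_postprocess(post, feats)
  } else {
    apply_zscore(post, feats)
  }
  clf <- train_classifier(config$classifier, X, segments$meta$label)
  structure(list(config = config, csp_model = csp_model, post = post,
                 classifier = clf),
            class = "pipeline_model")
}

#' Predict dream/dreamless labels for a segment set
#'
#' @param model A `pipeline_model` from [fit_pipeline()].
#' @param segments A `segment_set`.
#' @return List with `pred` (0/1) and `score` (continuous class-1 score).
#' @export
predict_pipeline <- function(model, segments) {
  feats <- raw_features(model$config, segments, model$csp_model)
  X <- if (model$config$feature == "csp") {
    apply_feature_postprocess(model$post, feats)
  } else {
    apply_zscore(model$post, feats)
  }
  predict_classifier(model$classifier, X)
}

# One train/test round. For the DWT path the raw feature matrix of the
# whole set may be precomputed (it does not depend on the training side;
# only the z-scoring statistics do) and is then subset by row.
pipeline_fold <- function(segments, config, train, test, Xraw = NULL) {
  if (config$feature == "dwt" && !is.null(Xraw)) {
    post <- fit_zscore(Xraw[train, , drop = FALSE])
    clf <- train_classifier(config$classifier,
                            apply_zscore(post, Xraw[train, , drop = FALSE]),
                            segments$meta$label[train])
    out <- predict_classifier(clf, apply_zscore(post, Xraw[test, , drop = FALSE]))
  } else {
    model <- fit_pipeline(subset_segments(segments, train), config)
    out <- predict_pipeline(model, subset_segments(segments, test))
  }
  out
}

precompute_raw <- function(segments, config) {
  if (config$feature == "dwt") {
    dwt_feature_matrix(segments, config$wavelet, config$levels, config$kmax)
  } else {
    NULL
  }
}

#' Cross-validated evaluation
#'
#' For every fold of the plan, fits the feature extractors and classifier
#' on the training side only, scores the held-out side, and aggregates the
#' five metrics as mean and standard deviation across folds, storing the
#' per-fold confusion matrices.
#'
#' @param segments A `segment_set`.
#' @param config A [pipeline_config()].
#' @param cvplan A `cv_plan` from [make_cv_splits()]; default is a seeded
#'   stratified 10-fold plan.
#' @return An `evaluation_report`.
#' @export
crossval_evaluate <- function(segments, config, cvplan = NULL) {
  cvplan <- cvplan %||% make_cv_splits(segments, "stratified-k-fold", k = 10)
  Xraw <- precompute_raw(segments, config)
  fold_metrics <- list()
  confusions <- list()
  for (f in seq_along(cvplan$folds)) {
    fold <- cvplan$folds[[f]]
    if (length(unique(segments$meta$label[fold$train])) < 2) {
      stopf("fold %d has single-class training data", f)
    }
    y_test <- segments$meta$label[fold$test]
    out <- pipeline_fold(segments, config, fold$train, fold$test, Xraw)
    ms <- suppressWarnings(compute_metrics(y_test, out$pred, out$score))
    fold_metrics[[f]] <- metrics_to_row(ms)
    confusions[[f]] <- confusion_counts(y_test, out$pred)
  }
  make_report(fold_metrics, confusions,
              config_echo = list(feature = config$feature,
                                 classifier = config$classifier$name,
                                 scheme = cvplan$scheme,
                                 folds = length(cvplan$folds)))
}

#' Single stratified train/test split evaluation
#'
#' Seeded stratified split (default 70/30), fit on the training side,
#' metrics on the held-out side.
#'
#' @param segments A `segment_set`.
#' @param config A [pipeline_config()].
#' @param train_frac Training fraction (default 0.7).
#' @param seed Split seed.
#' @return List with `metrics` (a `metric_set`), `confusion`, and the index
#'   vectors `train`/`test`.
#' @export
single_split_evaluate <- function(segments, config, train_frac = 0.7, seed = 1L) {
  y <- segments$meta$label
  idx_train <- with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      cl_idx <- which(y == cl)
      sample(cl_idx, max(1, round(train_frac * length(cl_idx))))
    }))
  })
  idx_test <- setdiff(seq_along(y), idx_train)
  model <- fit_pipeline(subset_segments(segments, idx_train), config)
  test <- subset_segments(segments, idx_test)
  out <- predict_pipeline(model, test)
  ms <- suppressWarnings(compute_metrics(test$meta$label, out$pred, out$score))
  list(metrics = ms, confusion = confusion_counts(test$meta$label, out$pred),
       train = idx_train, test = idx_test)
}

#' Leave-one-subject-out evaluation
#'
#' Trains on all subjects but one and scores the held-out subject,
#' repeating for every subject. Subjects whose data is single-class have no
#' defined AUROC; it is recorded as missing and excluded from the AUROC
#' mean (noted in the report). Summaries are also given for the two
#' imbalance strata: held-out subjects whose minority-class share is >= 20%
#' versus < 20%.
#'
#' @param segments A `segment_set` with >= 2 subjects.
#' @param config A [pipeline_config()].
#' @return List with `per_subject` (data frame of metrics), `overall`,
#'   `strata` (summaries for the two imbalance groups) and `notes`.
#' @export
loso_evaluate <- function(segments, config) {
  plan <- make_cv_splits(segments, "loso")
  Xraw <- precompute_raw(segments, config)
  subj <- vapply(plan$folds, function(f) segments$meta$subject_id[f$test[1]], "")
  rows <- list()
  notes <- character(0)
  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    out <- pipeline_fold(segments, config, fold$train, fold$test, Xraw)
    ms <- suppressWarnings(compute_metrics(segments$meta$label[fold$test],
                                           out$pred, out$score))
    if (is.na(ms$auroc)) {
      notes <- c(notes, sprintf(
        "subject %s: single-class data; AUROC undefined, excluded from mean", subj[i]))
    }
    lab <- segments$meta$label[fold$test]
    minority <- min(mean(lab == 0), mean(lab == 1))
    rows[[i]] <- data.frame(subject_id = subj[i], t(metrics_to_row(ms)),
                            minority_frac = minority,
                            stringsAsFactors = FALSE)
  }
  per_subject <- do.call(rbind, rows)
  summarize <- function(df) {
    if (nrow(df) == 0) return(NULL)
    list(n = nrow(df),
         mean = colMeans(df[metric_names], na.rm = TRUE),
         sd = apply(df[metric_names], 2, stats::sd, na.rm = TRUE))
  }
  list(per_subject = per_subject,
       overall = summarize(per_subject),
       strata = list(
         minority_ge_20 = summarize(per_subject[per_subject$minority_frac >= 0.2, ]),
         minority_lt_20 = summarize(per_subject[per_subject$minority_frac < 0.2, ])),
       notes = notes)
}

#' Random-label null experiment
#'
#' Trains on the true labels of each fold, then replaces the test labels
#' with independent draws at the requested class distribution, repeating
#' `reps` times and averaging. Under this null, all metrics concentrate at
#' their chance values, which exposes how accuracy alone can mislead on
#' imbalanced data.
#'
#' @param segments A `segment_set`.
#' @param config A [pipeline_config()].
#' @param dist Two probabilities `(p0, p1)` summing to 1, neither 0 nor 1.
#' @param reps Number of random relabelings per fold (default 10).
#' @param cvplan Optional `cv_plan` (default stratified 10-fold).
#' @param seed Seed for the label draws.
#' @return An `evaluation_report` whose rows are fold-by-rep averages.
#' @export
random_label_null <- function(segments, config, dist = c(0.5, 0.5), reps = 10,
                              cvplan = NULL, seed = 1L) {
  if (abs(sum(dist) - 1) > 1e-9) stopf("'dist' must sum to 1")
  if (any(dist <= 0) || any(dist >= 1)) stopf("'dist' must be non-degenerate")
  cvplan <- cvplan %||% make_cv_splits(segments, "stratified-k-fold", k = 10)
  Xraw <- precompute_raw(segments, config)
  fold_metrics <- list()
  confusions <- list()
  with_seed(seed, {
    for (f in seq_along(cvplan$folds)) {
      fold <- cvplan$folds[[f]]
      out <- pipeline_fold(segments, config, fold$train, fold$test, Xraw)
      rep_rows <- matrix(NA_real_, nrow = reps, ncol = length(metric_names))
      for (r in seq_len(reps)) {
        y_null <- sample(c(0, 1), length(fold$test), replace = TRUE, prob = dist)
        ms <- suppressWarnings(compute_metrics(y_null, out$pred, out$score))
        rep_rows[r, ] <- metrics_to_row(ms)
      }
      fold_metrics[[f]] <- colMeans(rep_rows, na.rm = TRUE)
      names(fold_metrics[[f]]) <- metric_names
      confusions[[f]] <- NULL
    }
  })
  make_report(fold_metrics, NULL,
              config_echo = list(feature = config$feature,
                                 classifier = config$classifier$name,
                                 null_dist = dist, reps = reps))
}
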
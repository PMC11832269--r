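# Permutation-based channel importance: the drop in held-out performance
# when one channel's data is randomly reassigned across test instances,
# relative to the unperturbed baseline of the same fold. Channels whose
# shuffling hurts the most are the most informative.

#' Permute one channel across test instances
#'
#' Reassigns the designated channel's time series across segments by a
#' uniform random permutation (fixed points allowed); all other channels
#' and every within-channel time series are untouched, so the per-channel
#' data multiset is preserved.
#'
#' @param segments A `segment_set`.
#' @param channel_index Channel to permute (1-based).
#' @param seed Seed for the permutation draw.
#' @return A `segment_set` with the channel reassigned.
#' @export
permute_channel <- function(segments, channel_index, seed = 1L) {
  n_ch <- dim(segments$x)[1]
  if (!is_count(channel_index) || channel_index > n_ch) {
    stopf("invalid channel index %s", channel_index)
  }
  n <- n_segments(segments)
  if (n < 2) {
    warnf("single test instance; permutation is the identity")
    return(segments)
  }
  perm <- with_seed(seed, sample(n))
  x <- segments$x
  x[channel_index, , ] <- x[channel_index, , perm]
  segment_set(x, segments$meta, segments$fs, segments$segment_len,
              segments$channel_names)
}

#' Permutation-based channel importance
#'
#' Per cross-validation fold: fit the pipeline on the training side,
#' measure baseline metrics on the held-out side, then permute each channel
#' in turn across test instances and re-score. The per-channel importance
#' is the baseline-minus-permuted delta averaged over folds, with the final
#' ranking key the mean delta across the five metrics (ties broken by the
#' accuracy delta, then channel index). The trained models are never
#' refitted during permutation.
#'
#' @param segments A `segment_set`.
#' @param config A [pipeline_config()].
#' @param folds Number of stratified folds (default 10).
#' @param seed Seed for fold assignment and permutation draws.
#' @param permute_reps Permutation draws averaged per fold-channel
#'   (default 1, the single-draw variant; increase for variance reduction).
#' @return A `channel_importance` object: data frame `table` with one row
#'   per channel (per-metric delta, average delta, rank), plus `baseline`
#'   (per-fold baseline metric matrix) and `folds`.
#' @export
channel_importance <- function(segments, config, folds = 10, seed = 1L,
                               permute_reps = 1) {
  n_ch <- dim(segments$x)[1]
  if (n_ch < 2) stopf("channel importance requires >= 2 channels")
  plan <- make_cv_splits(segments, "stratified-k-fold", k = folds, seed = seed)
  deltas <- array(0, dim = c(length(plan$folds), n_ch, length(metric_names)),
                  dimnames = list(NULL, segments$channel_names, metric_names))
  baseline <- matrix(NA_real_, nrow = length(plan$folds),
                     ncol = length(metric_names),
                     dimnames = list(NULL, metric_names))
  draw <- 0L
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    model <- fit_pipeline(subset_segments(segments, fold$train), config)
    test <- subset_segments(segments, fold$test)
    out <- predict_pipeline(model, test)
    base <- metrics_to_row(
      suppressWarnings(compute_metrics(test$meta$label, out$pred, out$score)))
    baseline[f, ] <- base
    for (ch in seq_len(n_ch)) {
      acc <- numeric(length(metric_names))
      for (r in seq_len(permute_reps)) {
        draw <- draw + 1L
        perm_test <- permute_channel(test, ch, seed = seed + 1000L * draw)
        pout <- predict_pipeline(model, perm_test)
        acc <- acc + metrics_to_row(
          suppressWarnings(compute_metrics(perm_test$meta$label, pout$pred,
                                           pout$score)))
      }
      deltas[f, ch, ] <- base - acc / permute_reps
    }
  }
  per_metric <- apply(deltas, c(2, 3), mean, na.rm = TRUE)
  avg <- rowMeans(per_metric)
  ord <- order(-avg, -per_metric[, "accuracy"], seq_len(n_ch))
  tab <- data.frame(channel = segments$channel_names,
                    per_metric, average = avg,
                    rank = match(seq_len(n_ch), ord),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, baseline = baseline, folds = length(plan$folds)),
            class = "channel_importance")
}

#' @export
print.channel_importance <- function(x, ...) {
  cat(sprintf("<channel_importance> %d channels over %d folds; top 5:\n",
              nrow(x$table), x$folds))
  top <- x$table[order(x$table$rank), ][1:min(5, nrow(x$table)), c("channel", "average", "rank")]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Ranked channels from an importance table
#'
#' @param importance A `channel_importance`.
#' @return Character vector of channel names, most important first.
#' @export
ranked_channels <- function(importance) {
  importance$table$channel[order(importance$table$rank)]
}

#' Performance curve over the k most important channels
#'
#' For each requested k, restricts the data to the k top-ranked channels,
#' retrains and evaluates the full pipeline by cross-validation, and
#' reports the metric-versus-k table.
#'
#' @param segments The `segment_set` the importance was computed on.
#' @param importance A `channel_importance`.
#' @param ks Channel counts to evaluate.
#' @param config A [pipeline_config()].
#' @param folds CV folds per point (default 10).
#' @param seed Fold seed.
#' @return List with `table` (data frame: k plus mean metrics) and
#'   `reports` (per-k `evaluation_report`s).
#' @export
topk_curve <- function(segments, importance, ks, config, folds = 10, seed = 1L) {
  n_ch <- dim(segments$x)[1]
  if (any(ks > n_ch)) stopf("k exceeds channel count %d", n_ch)
  ranking <- ranked_channels(importance)
  reports <- list()
  rows <- list()
  for (k in ks) {
    sub <- restrict_channels(segments, ranking[seq_len(k)])
    plan <- make_cv_splits(sub, "stratified-k-fold", k = folds, seed = seed)
    rep <- crossval_evaluate(sub, config, plan)
    reports[[as.character(k)]] <- rep
    rows[[as.character(k)]] <- c(k = k, rep$mean)
  }
  list(table = as.data.frame(do.call(rbind, rows)), reports = reports)
}
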
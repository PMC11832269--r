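# Binary classification metrics with the dream state (label 1) as the
# positive class.

#' Compute the five evaluation metrics
#'
#' Accuracy, F-score, precision, recall and AUROC for one evaluation, with
#' the dream class (1) positive. Precision/recall use zero-division guards
#' (returning 0 with a warning); AUROC is the rank statistic over the
#' continuous class-1 scores (probability that a random positive outscores
#' a random negative, ties counted half). AUROC is `NA` when the truth is
#' single-class.
#'
#' @param y_true 0/1 ground-truth labels.
#' @param y_pred 0/1 predictions.
#' @param scores Continuous class-1 scores (for AUROC).
#' @return A `metric_set`: named list `accuracy`, `fscore`, `precision`,
#'   `recall`, `auroc`.
#' @export
compute_metrics <- function(y_true, y_pred, scores) {
  if (length(y_true) != length(y_pred) || length(y_true) != length(scores)) {
    stopf("y_true, y_pred and scores must have equal length")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  accuracy <- (tp + tn) / length(y_true)
  precision <- if (tp + fp == 0) {
    warnf("no positive predictions; precision set to 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    warnf("no positive instances; recall set to 0")
    0
  } else tp / (tp + fn)
  fscore <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  auroc <- auroc_rank(y_true, scores)
  structure(list(accuracy = accuracy, fscore = fscore, precision = precision,
                 recall = recall, auroc = auroc),
            class = "metric_set")
}

# Mann-Whitney AUROC from ranks; NA if one class absent.
auroc_rank <- function(y_true, scores) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %.3f  fscore %.3f  precision %.3f  recall %.3f  auroc %s\n",
              x$accuracy, x$fscore, x$precision, x$recall,
              ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc))))
  invisible(x)
}

metric_names <- c("accuracy", "fscore", "precision", "recall", "auroc")

metrics_to_row <- function(ms) {
  vapply(metric_names, function(m) ms[[m]] %||% NA_real_, numeric(1))
}

confusion_counts <- function(y_true, y_pred) {
  matrix(c(sum(y_true == 0 & y_pred == 0), sum(y_true == 0 & y_pred == 1),
           sum(y_true == 1 & y_pred == 0), sum(y_true == 1 & y_pred == 1)),
         nrow = 2, byrow = TRUE,
         dimnames = list(truth = c("dreamless", "dream"),
                         predicted = c("dreamless", "dream")))
}

# Aggregate a list of per-fold metric rows into an evaluation report.
make_report <- function(fold_metrics, confusions, config_echo = NULL) {
  tab <- do.call(rbind, fold_metrics)
  structure(
    list(per_fold = tab,
         mean = colMeans(tab, na.rm = TRUE),
         sd = apply(tab, 2, stats::sd, na.rm = TRUE),
         confusion = confusions,
         config = config_echo),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d folds\n", nrow(x$per_fold)))
  for (m in colnames(x$per_fold)) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}
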
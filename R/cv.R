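# Cross-validation plans and class balancing.

#' Build a cross-validation plan
#'
#' Supports stratified k-fold splitting (class ratio preserved within one
#' instance per fold) and leave-one-subject-out (LOSO, one fold per
#' subject). With `grouping = "by-report"` all segments originating from one
#' report are kept on the same side of every fold, preventing leakage of
#' within-report correlation between train and test.
#'
#' @param segments A `segment_set`.
#' @param scheme `"stratified-k-fold"` or `"loso"`.
#' @param k Number of folds for the stratified scheme (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param grouping `"none"` or `"by-report"`.
#' @return A `cv_plan`: list with `folds` (each with `train` and `test`
#'   integer indices), `scheme`, `grouping`.
#' @export
make_cv_splits <- function(segments, scheme = c("stratified-k-fold", "loso"),
                           k = 10, seed = 1L, grouping = c("none", "by-report")) {
  scheme <- match.arg(scheme)
  grouping <- match.arg(grouping)
  y <- segments$meta$label
  n <- length(y)
  if (length(unique(y)) < 2) stopf("cross-validation requires both classes present")

  folds <- if (scheme == "loso") {
    subj <- segments$meta$subject_id
    if (length(unique(subj)) < 2) stopf("LOSO requires at least 2 subjects")
    lapply(sort(unique(subj)), function(s) {
      test <- which(subj == s)
      list(train = setdiff(seq_len(n), test), test = test)
    })
  } else {
    if (n < k) stopf("need at least k = %d instances for k-fold", k)
    with_seed(seed, {
      assign_fold <- integer(n)
      if (grouping == "by-report") {
        rep_ids <- segments$meta$report_id
        reps <- unique(rep_ids)
        rep_lab <- vapply(reps, function(r) y[match(r, rep_ids)], numeric(1))
        rep_fold <- integer(length(reps))
        for (cl in unique(rep_lab)) {
          idx <- sample(which(rep_lab == cl))
          rep_fold[idx] <- rep_len(seq_len(k), length(idx))
        }
        assign_fold <- rep_fold[match(rep_ids, reps)]
      } else {
        for (cl in unique(y)) {
          idx <- sample(which(y == cl))
          assign_fold[idx] <- rep_len(seq_len(k), length(idx))
        }
      }
      lapply(seq_len(k), function(f) {
        test <- which(assign_fold == f)
        list(train = setdiff(seq_len(n), test), test = test)
      })
    })
  }
  structure(list(folds = folds, scheme = scheme, grouping = grouping),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %s (%s grouping), %d folds\n",
              x$scheme, x$grouping, length(x$folds)))
  invisible(x)
}

#' Balance classes by downsampling the majority class
#'
#' Keeps every minority-class segment and a uniformly random subset of the
#' majority class of the same size.
#'
#' @param segments A `segment_set` containing both classes.
#' @param seed Integer seed for the majority-class draw.
#' @return A balanced `segment_set`.
#' @export
balance_subset <- function(segments, seed = 1L) {
  y <- segments$meta$label
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 == 0 || n1 == 0) stopf("both classes must be present to balance")
  m <- min(n0, n1)
  with_seed(seed, {
    keep0 <- if (n0 > m) sample(which(y == 0), m) else which(y == 0)
    keep1 <- if (n1 > m) sample(which(y == 1), m) else which(y == 1)
    subset_segments(segments, sort(c(keep0, keep1)))
  })
}
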
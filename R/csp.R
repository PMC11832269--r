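# Common spatial patterns (CSP) feature path: supervised spatial filtering
# by a generalized eigendecomposition of the two class covariance matrices,
# followed by PCA and z-scoring fitted on training data only.
#
# Each segment's covariance is trace-normalized before class averaging
# (standard CSP conditioning against amplitude outliers); the filters solve
# the pencil (S1, S1 + S2), so the whitened-space eigenvalues of the two
# classes pair to one.

CSP_VAR_FLOOR <- 1e-12

#' Fit a CSP model
#'
#' Computes per-class average covariance (each segment covariance normalized
#' by its trace), whitens the composite covariance, and extracts spatial
#' filters ordered by descending class-1 eigenvalue. The number of
#' components defaults to the channel count, making the transform square.
#'
#' @param segments A `segment_set` (training side only).
#' @param labels Optional 0/1 labels; defaults to `segments$meta$label`.
#' @param shrinkage Shrinkage weight toward a scaled identity applied to the
#'   composite covariance for rank-deficiency safety (default 1e-6).
#' @return A `csp_model`: `spatial_filters` (components x channels),
#'   `eigenvalues` (whitened class-1 eigenvalues in [0,1]),
#'   `class_covariances`, `component_count`, `channel_names`.
#' @export
fit_csp <- function(segments, labels = NULL, shrinkage = 1e-6) {
  y <- labels %||% segments$meta$label
  if (length(unique(y)) != 2) stopf("fit_csp: exactly two classes required")
  if (min(table(y)) < 2) stopf("fit_csp: need >= 2 segments per class")
  x <- segments$x
  n_ch <- dim(x)[1]

  class_cov <- function(idx) {
    acc <- matrix(0, n_ch, n_ch)
    for (i in idx) {
      s <- matrix(x[, , i], nrow = n_ch)
      s <- s - rowMeans(s)
      cv <- tcrossprod(s) / (ncol(s) - 1)
      tr <- sum(diag(cv))
      if (tr > CSP_VAR_FLOOR) acc <- acc + cv / tr
    }
    acc / length(idx)
  }
  shrink <- function(s) {
    (1 - shrinkage) * s + shrinkage * (sum(diag(s)) / n_ch) * diag(n_ch)
  }
  # per-class shrinkage toward a scaled identity guards the whitening step
  # while keeping the two-class eigenvalue pairing exact
  s1 <- shrink(class_cov(which(y == 1)))
  s0 <- shrink(class_cov(which(y == 0)))
  sc <- s1 + s0

  ec <- eigen(sc, symmetric = TRUE)
  pos <- ec$values > max(ec$values) * 1e-10
  if (!all(pos)) warnf("fit_csp: composite covariance rank-deficient; regularized")
  vals <- pmax(ec$values, max(ec$values) * 1e-10)
  whiten <- diag(1 / sqrt(vals), nrow = length(vals)) %*% t(ec$vectors)
  ew <- eigen(whiten %*% s1 %*% t(whiten), symmetric = TRUE)
  ord <- order(ew$values, decreasing = TRUE)
  filters <- t(ew$vectors[, ord, drop = FALSE]) %*% whiten

  structure(
    list(spatial_filters = filters,
         eigenvalues = pmin(pmax(ew$values[ord], 0), 1),
         class_covariances = list(dreamless = s0, dream = s1),
         component_count = n_ch,
         channel_names = segments$channel_names),
    class = "csp_model"
  )
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d components over %d channels; top eigenvalue %.3f\n",
              x$component_count, length(x$channel_names), x$eigenvalues[1]))
  invisible(x)
}

#' CSP log-variance features
#'
#' Projects every segment onto the spatial filters and emits the log
#' variance of each component (one value per component per segment), the
#' canonical CSP segment representation. A variance floor of 1e-12 keeps
#' degenerate (near-constant) segments finite.
#'
#' @param model A fitted `csp_model`.
#' @param segments A `segment_set` with matching channel count.
#' @return Numeric matrix, segments x components.
#' @export
csp_features <- function(model, segments) {
  if (!inherits(model, "csp_model")) stopf("'model' must be a csp_model")
  n_ch <- dim(segments$x)[1]
  if (n_ch != ncol(model$spatial_filters)) {
    stopf("channel count mismatch: model %d vs data %d",
          ncol(model$spatial_filters), n_ch)
  }
  n_samp <- dim(segments$x)[2]
  n_seg <- dim(segments$x)[3]
  flat <- segments$x
  dim(flat) <- c(n_ch, n_samp * n_seg)
  proj <- model$spatial_filters %*% flat          # one BLAS call for all segments
  k <- nrow(proj)
  dim(proj) <- c(k, n_samp, n_seg)
  sums <- colSums(aperm(proj, c(2, 1, 3)))        # k x n_seg
  sq <- colSums(aperm(proj^2, c(2, 1, 3)))
  v <- (sq - sums^2 / n_samp) / (n_samp - 1)
  t(log(pmax(v, CSP_VAR_FLOOR)))
}

#' Fit the PCA + standardization feature postprocessor
#'
#' PCA retains `n_components` components (all of them by default, a pure
#' rotation when the feature dimension equals the component count), then
#' z-scoring statistics are computed on the rotated training rows.
#' Zero-variance columns get a unit standard deviation guard.
#'
#' @param train_features Numeric matrix of training rows.
#' @param n_components Number of PCA components (default: all).
#' @return A `feature_postprocessor`.
#' @export
fit_feature_postprocess <- function(train_features, n_components = NULL) {
  if (!is.matrix(train_features)) train_features <- as.matrix(train_features)
  if (nrow(train_features) < 2) stopf("need >= 2 training rows")
  n_components <- n_components %||% ncol(train_features)
  n_components <- min(n_components, ncol(train_features))
  pca_mean <- colMeans(train_features)
  centered <- sweep(train_features, 2, pca_mean)
  sv <- svd(centered, nu = 0, nv = n_components)
  rot <- sv$v
  scores <- centered %*% rot
  mu <- colMeans(scores)
  sd_ <- apply(scores, 2, stats::sd)
  zero <- sd_ < 1e-12
  if (any(zero)) {
    warnf("%d zero-variance feature(s); unit-sd guard applied", sum(zero))
    sd_[zero] <- 1
  }
  structure(
    list(pca_components = rot, pca_mean = pca_mean,
         standardizer_mean = mu, standardizer_sd = sd_),
    class = "feature_postprocessor"
  )
}

#' Apply a fitted feature postprocessor
#'
#' Applies the training-derived PCA rotation and z-scoring to any rows;
#' never refits.
#'
#' @param pp A `feature_postprocessor` from [fit_feature_postprocess()].
#' @param features Numeric matrix of rows to transform.
#' @return Transformed numeric matrix.
#' @export
apply_feature_postprocess <- function(pp, features) {
  if (!inherits(pp, "feature_postprocessor")) stopf("'pp' must be a feature_postprocessor")
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(pp$pca_mean)) {
    stopf("feature dimension mismatch: expected %d, got %d",
          length(pp$pca_mean), ncol(features))
  }
  scores <- sweep(features, 2, pp$pca_mean) %*% pp$pca_components
  sweep(sweep(scores, 2, pp$standardizer_mean), 2, pp$standardizer_sd, `/`)
}
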
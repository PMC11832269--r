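# Two-channel toy: class 1 carries signal only on channel 1, class 0 only
# on channel 2. The first CSP filter must then concentrate class-1 variance.
csp_toy <- function(n_per_class = 30, n_samp = 200, seed = 2) {
  set.seed(seed)
  x <- array(0, dim = c(2, n_samp, 2 * n_per_class))
  y <- rep(c(1, 0), each = n_per_class)
  for (i in seq_len(2 * n_per_class)) {
    x[, , i] <- rbind(rnorm(n_samp, sd = 0.05), rnorm(n_samp, sd = 0.05))
    ch <- if (y[i] == 1) 1 else 2
    x[ch, , i] <- x[ch, , i] + rnorm(n_samp)
  }
  meta <- data.frame(label = y, subject_id = "S1",
                     report_id = paste0("r", seq_along(y)), stage = "N2",
                     awake_assumed = FALSE)
  segment_set(x, meta, 100, n_samp / 100, c("c1", "c2"))
}

test_that("CSP concentrates class variance on the planted toy", {
  segs <- csp_toy()
  m <- fit_csp(segs)
  w1 <- m$spatial_filters[1, ]
  # brute-force variance of the first component per class
  v <- vapply(seq_len(n_segments(segs)),
              function(i) var(as.vector(w1 %*% segs$x[, , i])), numeric(1))
  y <- segs$meta$label
  expect_gte(mean(v[y == 1]) / mean(v[y == 0]), 10)

  # toy separation: class means of feature 1 separated by >= 2 pooled SDs
  f <- csp_features(m, segs)
  pooled <- sqrt((var(f[y == 1, 1]) + var(f[y == 0, 1])) / 2)
  expect_gte(abs(mean(f[y == 1, 1]) - mean(f[y == 0, 1])) / pooled, 2)
})

test_that("whitened class eigenvalues pair to one", {
  segs <- fx_signal16()
  m <- fit_csp(segs)
  # independent eigen-oracle: project both class covariances through the
  # filters; the diagonal pair sums must be 1 for every component
  w <- m$spatial_filters
  l1 <- diag(w %*% m$class_covariances$dream %*% t(w))
  l0 <- diag(w %*% m$class_covariances$dreamless %*% t(w))
  expect_lt(max(abs(l1 + l0 - 1)), 1e-8)
  expect_equal(unname(l1), unname(m$eigenvalues), tolerance = 1e-8)
  expect_true(all(m$eigenvalues >= 0 & m$eigenvalues <= 1))
  expect_equal(m$eigenvalues, sort(m$eigenvalues, decreasing = TRUE))
})

test_that("exchangeable classes give eigenvalues near one half", {
  segs <- fx_null16()
  m <- fit_csp(segs)
  expect_lt(max(abs(m$eigenvalues - 0.5)), 0.1)
  mid <- m$eigenvalues[4:13]  # away from the extremes of sampling noise
  expect_lt(max(abs(mid - 0.5)), 0.05)
})

test_that("log-variance features obey the scaling identity and stay finite", {
  segs <- csp_toy(n_per_class = 10)
  m <- fit_csp(segs)
  one <- subset_segments(segs, 1)
  f1 <- csp_features(m, one)
  doubled <- one
  doubled$x <- doubled$x * 2
  f2 <- csp_features(m, doubled)
  expect_equal(as.vector(f2 - f1), rep(log(4), ncol(f1)), tolerance = 1e-9)

  # constant-zero segment: variance floor keeps the output finite
  zero <- one
  zero$x[] <- 0
  expect_true(all(is.finite(csp_features(m, zero))))

  bad <- fx_manual_segments(n_ch = 5)
  expect_error(csp_features(m, bad), "mismatch")
})

test_that("fit_csp rejects degenerate class structure", {
  segs <- csp_toy(n_per_class = 10)
  segs$meta$label <- rep(1, n_segments(segs))
  expect_error(fit_csp(segs), "two classes")
})

test_that("postprocessor z-scores training rows and inverts its rotation", {
  set.seed(7)
  f <- matrix(rnorm(600), 100, 6) %*% diag(c(5, 3, 1, 1, 0.5, 0.1))
  pp <- fit_feature_postprocess(f)
  z <- apply_feature_postprocess(pp, f)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)

  # full-rank PCA is a rotation: inverse reproduces the centered features
  centered <- sweep(f, 2, colMeans(f))
  back <- (z * matrix(pp$standardizer_sd, 100, 6, byrow = TRUE) +
           matrix(pp$standardizer_mean, 100, 6, byrow = TRUE)) %*% t(pp$pca_components)
  expect_lt(max(abs(back - centered)), 1e-8)

  # constant column maps to zero under the unit-sd guard
  f2 <- cbind(f[, 1:2], 3)
  expect_warning(pp2 <- fit_feature_postprocess(f2), "zero-variance")
  z2 <- apply_feature_postprocess(pp2, f2)
  expect_true(all(abs(z2[, ncol(z2)]) < 1e-9))

  expect_error(fit_feature_postprocess(f[1, , drop = FALSE]), "2 training rows")
  expect_error(apply_feature_postprocess(pp, f[, 1:3]), "mismatch")
  # single row transforms fine
  expect_equal(dim(apply_feature_postprocess(pp, f[1, , drop = FALSE])), c(1, 6))
})

test_that("the fitted CSP model is independent of test data", {
  segs <- fx_signal16()
  idx <- seq_len(n_segments(segs))
  train <- subset_segments(segs, idx[idx %% 3 != 0])
  m1 <- fit_csp(train)
  # corrupt the held-out segments; refit on the same training side
  segs$x[, , idx %% 3 == 0] <- 0
  train2 <- subset_segments(segs, idx[idx %% 3 != 0])
  m2 <- fit_csp(train2)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
})
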
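# Per-sub-band feature battery: four fractal-dimension estimators, two
# log-scale energies, the two Hjorth descriptors, and the third and fourth
# standardized moments. Ten features per sub-band, five sub-bands per
# channel, concatenated channel-major into one vector per segment.

ENERGY_FLOOR <- 1e-12

#' Katz fractal dimension
#'
#' `FD = log10(n) / (log10(n) + log10(d / L))` with `L` the total polyline
#' length over a unit-index abscissa, `d` the maximum distance from the
#' first point, and `n = L / a` where `a` is the mean step length.
#' Constant signals return 1 by guard.
#'
#' @param x Numeric vector, length >= 3.
#' @return Dimensionless fractal dimension estimate.
#' @export
katz_fd <- function(x) {
  if (length(x) < 3) stopf("katz_fd: need length >= 3")
  dy <- diff(x)
  steps <- sqrt(1 + dy^2)
  L <- sum(steps)
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  if (d < .Machine$double.eps || stats::sd(x) < .Machine$double.eps) return(1)
  n <- L / mean(steps)
  log10(n) / (log10(n) + log10(d / L))
}

#' Petrosian fractal dimension
#'
#' `FD = log10(n) / (log10(n) + log10(n / (n + 0.4 * Nd)))` where `Nd`
#' counts sign changes of the first difference.
#'
#' @param x Numeric vector, length >= 3.
#' @return Dimensionless fractal dimension estimate.
#' @export
petrosian_fd <- function(x) {
  if (length(x) < 3) stopf("petrosian_fd: need length >= 3")
  n <- length(x)
  dx <- diff(x)
  s <- sign(dx)
  nd <- sum(s[-1] * s[-length(s)] < 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

#' Higuchi fractal dimension
#'
#' Least-squares slope of `log(L(k))` against `log(1/k)` for
#' `k = 1..kmax`, where `L(k)` is Higuchi's normalized mean curve length at
#' scale `k`.
#'
#' @param x Numeric vector, length >= 2 * kmax.
#' @param kmax Maximum scale (default 10).
#' @return Dimensionless fractal dimension estimate (about 1 for smooth
#'   curves, about 2 for white noise).
#' @export
higuchi_fd <- function(x, kmax = 10) {
  if (!is_count(kmax) || kmax < 2) stopf("higuchi_fd: kmax must be an integer >= 2")
  n <- length(x)
  if (n < 2 * kmax) stopf("higuchi_fd: need length >= 2 * kmax")
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm_ <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1
      if (ni < 1) { lm_[m] <- NA_real_; next }
      lm_[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (ni * k) / k
    }
    lk[k] <- mean(lm_, na.rm = TRUE)
  }
  ok <- lk > 0
  if (sum(ok) < 2) return(1)
  stats::coef(stats::lm(log(lk[ok]) ~ log(1 / seq_len(kmax)[ok])))[2]
}

#' Sevcik fractal dimension
#'
#' Normalizes the waveform into the unit square and evaluates
#' `FD = 1 + ln(L) / ln(2 * (n - 1))` with `L` the normalized polyline
#' length. Constant signals return 1 by guard.
#'
#' @param x Numeric vector, length >= 2.
#' @return Dimensionless fractal dimension estimate.
#' @export
sevcik_fd <- function(x) {
  n <- length(x)
  if (n < 2) stopf("sevcik_fd: need length >= 2")
  rng <- max(x) - min(x)
  if (rng < .Machine$double.eps) return(1)
  ys <- (x - min(x)) / rng
  xs <- (seq_len(n) - 1) / (n - 1)
  L <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  1 + log(L) / log(2 * (n - 1))
}

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(diff(x)) / var(x))`; complexity is the mobility of
#' the first difference divided by the mobility of the signal. Zero-variance
#' input returns `(0, 0)` with a warning.
#'
#' @param x Numeric vector, length >= 3.
#' @return Named numeric vector `c(mobility, complexity)`.
#' @export
hjorth_params <- function(x) {
  if (length(x) < 3) stopf("hjorth_params: need length >= 3")
  v0 <- stats::var(x)
  if (v0 < ENERGY_FLOOR) {
    warnf("hjorth_params: zero-variance signal; returning (0, 0)")
    return(c(mobility = 0, complexity = 0))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  cmp <- if (v1 < ENERGY_FLOOR) 0 else sqrt(v2 / v1) / mob
  c(mobility = mob, complexity = cmp)
}

#' Instantaneous and Teager energies (log2 scale)
#'
#' Instantaneous energy is `log2(mean(x^2))`; Teager energy is
#' `log2(mean(|x_i^2 - x_(i-1) * x_(i+1)|))` over the interior points. Both
#' are floored at 1e-12 before the logarithm, so a zero signal maps to
#' `log2(1e-12)`.
#'
#' @param x Numeric vector, length >= 3.
#' @return Named numeric vector `c(instantaneous, teager)`.
#' @export
energy_features <- function(x) {
  if (length(x) < 3) stopf("energy_features: need length >= 3")
  n <- length(x)
  inst <- log2(max(mean(x^2), ENERGY_FLOOR))
  core <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  teager <- log2(max(sum(abs(core)) / (n - 2), ENERGY_FLOOR))
  c(instantaneous = inst, teager = teager)
}

#' Skewness and excess kurtosis
#'
#' Standardized third central moment and Fisher excess kurtosis (a Gaussian
#' gives 0). Zero-variance input returns `(0, 0)` by guard; both statistics
#' are translation invariant.
#'
#' @param x Numeric vector, length >= 4.
#' @return Named numeric vector `c(skewness, kurtosis)`.
#' @export
moment_features <- function(x) {
  if (length(x) < 4) stopf("moment_features: need length >= 4")
  m2 <- mean((x - mean(x))^2)
  if (m2 < ENERGY_FLOOR) return(c(skewness = 0, kurtosis = 0))
  c(skewness = e1071::skewness(x, type = 1),
    kurtosis = e1071::kurtosis(x, type = 1))
}

dwt_feature_names <- c("sevcik_fd", "katz_fd", "petrosian_fd", "higuchi_fd",
                       "inst_energy", "teager_energy", "hjorth_mobility",
                       "hjorth_complexity", "kurtosis", "skewness")

subband_features <- function(cf, kmax) {
  hj <- hjorth_params_quiet(cf)
  en <- energy_features(cf)
  mo <- moment_features(cf)
  hig <- if (length(cf) >= 2 * kmax) higuchi_fd(cf, kmax) else
    higuchi_fd(cf, max(2, length(cf) %/% 2))
  c(sevcik_fd(cf), katz_fd(cf), petrosian_fd(cf), hig,
    en[["instantaneous"]], en[["teager"]],
    hj[["mobility"]], hj[["complexity"]],
    mo[["kurtosis"]], mo[["skewness"]])
}

# zero-variance sub-bands are legitimate (e.g. zero signals); keep quiet
hjorth_params_quiet <- function(x) suppressWarnings(hjorth_params(x))

#' DWT feature vector for one segment
#'
#' Decomposes every channel with [dwt_decompose()] and computes the
#' ten-feature battery on each of the five sub-bands. Ordering is pinned as
#' channel-major, sub-bands from the level-4 approximation down to the
#' level-1 detail, features in the order sevcik_fd, katz_fd, petrosian_fd,
#' higuchi_fd, inst_energy, teager_energy, hjorth_mobility,
#' hjorth_complexity, kurtosis, skewness. The vector length is therefore
#' `channels * 5 * 10` (2900 for a 58-channel montage).
#'
#' @param segment Numeric matrix, channels x samples.
#' @param wavelet Wavelet name (default `"bior2.2"`).
#' @param levels Decomposition levels (default 4).
#' @param kmax Higuchi scale cap (default 10).
#' @param channel_names Optional channel labels used for feature names.
#' @return Named numeric vector (`ch.band.feature` naming).
#' @export
extract_dwt_vector <- function(segment, wavelet = "bior2.2", levels = 4,
                               kmax = 10, channel_names = NULL) {
  if (!is.matrix(segment)) segment <- matrix(segment, nrow = 1)
  n_ch <- nrow(segment)
  channel_names <- channel_names %||% paste0("ch", seq_len(n_ch))
  out <- numeric(0)
  nm <- character(0)
  for (ch in seq_len(n_ch)) {
    dec <- dwt_decompose(segment[ch, ], wavelet, levels)
    for (b in names(dec$coefficients)) {
      out <- c(out, subband_features(dec$coefficients[[b]], kmax))
      nm <- c(nm, paste(channel_names[ch], b, dwt_feature_names, sep = "."))
    }
  }
  names(out) <- nm
  out
}

#' DWT feature matrix for a segment set
#'
#' Applies [extract_dwt_vector()] to every segment.
#'
#' @param segments A `segment_set`.
#' @inheritParams extract_dwt_vector
#' @return Numeric matrix, segments x features.
#' @export
dwt_feature_matrix <- function(segments, wavelet = "bior2.2", levels = 4,
                               kmax = 10) {
  n <- n_segments(segments)
  rows <- lapply(seq_len(n), function(i) {
    extract_dwt_vector(segments$x[, , i, drop = TRUE], wavelet, levels, kmax,
                       segments$channel_names)
  })
  do.call(rbind, rows)
}
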
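# Multilevel discrete wavelet transform with the biorthogonal 2.2 filter
# bank and half-point symmetric boundary extension (the convention of
# mainstream wavelet libraries, which fixes coefficient-array lengths at
# floor((n + L - 1) / 2) per step and gives perfect reconstruction).
#
# Filter taps are exact dyadic rationals times sqrt(2).

dwt_filter_banks <- list(
  bior2.2 = {
    s <- sqrt(2) / 8
    list(dec_lo = s * c(0, -1, 2, 6, 2, -1),
         dec_hi = s * c(0, 2, -4, 2, 0, 0),
         rec_lo = s * c(0, 2, 4, 2, 0, 0),
         rec_hi = s * c(0, 1, 2, -6, 2, 1))
  }
)

dwt_bank <- function(wavelet) {
  bank <- dwt_filter_banks[[wavelet]]
  if (is.null(bank)) {
    stopf("unknown wavelet '%s' (available: %s)", wavelet,
          paste(names(dwt_filter_banks), collapse = ", "))
  }
  bank
}

conv_full <- function(x, f) stats::convolve(x, rev(f), type = "open")

# One analysis step: symmetric extension by L-1, filter, dyadic downsample.
# Requires n >= L - 1, which dwt_decompose's minimum-length check enforces
# at every level.
dwt_step <- function(x, bank) {
  L <- length(bank$dec_lo)
  n <- length(x)
  ext <- c(rev(x[seq_len(L - 1)]), x, rev(x)[seq_len(L - 1)])
  idx <- seq(L + 1, by = 2, length.out = floor((n + L - 1) / 2))
  list(a = conv_full(ext, bank$dec_lo)[idx],
       d = conv_full(ext, bank$dec_hi)[idx])
}

# One synthesis step: dyadic upsample, filter, overlap-add, trim L-2 margin.
idwt_step <- function(a, d, bank) {
  L <- length(bank$rec_lo)
  up <- function(cf) {
    u <- numeric(2 * length(cf))
    u[seq(1, by = 2, length.out = length(cf))] <- cf
    u
  }
  y <- conv_full(up(a), bank$rec_lo) + conv_full(up(d), bank$rec_hi)
  y[seq(L - 1, length.out = 2 * length(a) - L + 2)]
}

#' Multilevel DWT decomposition of one channel
#'
#' Decomposes a 1-D signal into one approximation array plus `levels`
#' detail arrays (coarsest first) using iterated analysis filter pairs.
#'
#' @param x Numeric vector.
#' @param wavelet Wavelet name; `"bior2.2"` is the only built-in bank.
#' @param levels Number of decomposition levels (default 4, yielding five
#'   sub-bands).
#' @return A `subband_decomposition`: list with `coefficients` (named list
#'   `a4, d4, d3, d2, d1` for four levels), `wavelet`, `levels`, `lengths`
#'   (per-level input lengths, needed for reconstruction).
#' @export
dwt_decompose <- function(x, wavelet = "bior2.2", levels = 4) {
  bank <- dwt_bank(wavelet)
  L <- length(bank$dec_lo)
  if (!is_count(levels)) stopf("'levels' must be a positive integer")
  min_len <- L - 1
  for (lv in seq_len(levels - 1)) min_len <- 2 * min_len  # need n >= L-1 at each level
  if (length(x) < min_len) {
    stopf("signal of length %d too short for %d levels (need >= %d samples)",
          length(x), levels, min_len)
  }
  coeffs <- vector("list", levels + 1)
  lens <- integer(levels)
  cur <- as.numeric(x)
  for (lv in seq_len(levels)) {
    lens[lv] <- length(cur)
    st <- dwt_step(cur, bank)
    coeffs[[levels + 2 - lv]] <- st$d
    cur <- st$a
  }
  coeffs[[1]] <- cur
  names(coeffs) <- c(paste0("a", levels), paste0("d", levels:1))
  structure(list(coefficients = coeffs, wavelet = wavelet, levels = levels,
                 lengths = lens),
            class = "subband_decomposition")
}

#' Reconstruct a signal from its DWT decomposition
#'
#' Inverse of [dwt_decompose()]; reconstruction is exact to floating-point
#' rounding.
#'
#' @param decomp A `subband_decomposition`.
#' @return Numeric vector of the original length.
#' @export
dwt_reconstruct <- function(decomp) {
  bank <- dwt_bank(decomp$wavelet)
  levels <- decomp$levels
  cur <- decomp$coefficients[[1]]
  for (lv in seq_len(levels)) {
    d <- decomp$coefficients[[1 + lv]]
    cur <- idwt_step(cur, d, bank)
    target <- decomp$lengths[levels + 1 - lv]
    cur <- cur[seq_len(target)]
  }
  cur
}
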
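#' Raw autocorrelation of a signal
#'
#' Computes the (unnormalized, zero-padded) autocorrelation
#' \eqn{r_m = \sum_n x[n] x[n+m]} for lags `0..max_lag`, the right-hand
#' side of the all-pole normal equations.
#'
#' @param x Numeric sample vector.
#' @param max_lag Largest lag (must be `< length(x)`).
#' @return Numeric vector `r_0..r_max_lag` of length `max_lag + 1`.
#' @export
autocorrelation <- function(x, max_lag) {
  max_lag <- as.integer(max_lag)
  n <- length(x)
  if (max_lag >= n)
    stopf("'max_lag' (%d) must be smaller than length(x) (%d)", max_lag, n)
  if (max_lag < 0L) stopf("'max_lag' must be >= 0")
  r <- numeric(max_lag + 1L)
  for (m in 0:max_lag)
    r[m + 1L] <- sum(x[seq_len(n - m)] * x[(m + 1L):n])
  r
}

#' Fit an all-pole model by the Levinson-Durbin recursion
#'
#' Solves the Toeplitz normal equations of linear prediction in
#' \eqn{O(P^2)}: the returned `predictor_coeffs` \eqn{a_1..a_P} minimize
#' the mean-squared error of \eqn{\hat L[k] = \sum_m a_m L[k-m]}. The
#' corresponding all-pole synthesis filter is
#' \eqn{H(z) = G / (1 + \sum_j A_j z^{-j})} with denominator
#' coefficients \eqn{A_j = -a_j}, gain \eqn{G = \sqrt{E_P}} (unit-variance
#' excitation convention), and residual power
#' \eqn{E_P = r_0 - \sum_m a_m r_m}.
#'
#' The autocorrelation method guarantees all reflection coefficients have
#' magnitude < 1 (a minimum-phase, stable model); a reflection magnitude
#' reaching 1 is reported as a conditioning error naming the stage.
#'
#' @param r Autocorrelation sequence `r_0..` of length at least
#'   `order + 1`, with `r[1] > 0`.
#' @param order Prediction order P (>= 0).
#' @return An object of class `"lpc_model"` with fields `order`,
#'   `predictor_coeffs`, `denominator_coeffs`, `gain`, `error_power` and
#'   `reflection` (the P reflection coefficients).
#' @examples
#' levinson_durbin(c(1, 0.9, 0.81), 1)$predictor_coeffs  # AR(1): 0.9
#' @export
levinson_durbin <- function(r, order) {
  order <- as.integer(order)
  if (order < 0L) stopf("'order' must be >= 0")
  if (length(r) < order + 1L)
    stopf("need %d autocorrelation lags for order %d, got %d",
          order + 1L, order, length(r))
  if (!is.finite(r[1]) || r[1] <= 0)
    stopf("degenerate signal: zero-lag autocorrelation is not positive")
  a <- numeric(0)
  E <- r[1]
  ks <- numeric(order)
  for (m in seq_len(order)) {
    acc <- r[m + 1L]
    if (m > 1L) acc <- acc - sum(a * r[m:2])
    k <- acc / E
    if (!is.finite(k) || abs(k) >= 1)
      stopf("Levinson-Durbin recursion ill-conditioned at stage %d (|reflection| = %g)",
            m, abs(k))
    ks[m] <- k
    a <- if (m > 1L) c(a - k * rev(a), k) else k
    E <- E * (1 - k^2)
  }
  structure(
    list(order = order, predictor_coeffs = a, denominator_coeffs = -a,
         gain = sqrt(E), error_power = E, reflection = ks),
    class = "lpc_model")
}

#' @export
print.lpc_model <- function(x, ...) {
  cat(sprintf("<lpc_model> order %d, gain %.4g, error power %.4g\n",
              x$order, x$gain, x$error_power))
  invisible(x)
}

#' Sample the all-pole spectral envelope on a uniform frequency grid
#'
#' Evaluates the magnitude of the all-pole transfer function on the unit
#' circle, \eqn{|H(e^{i\omega})| = G / |1 + \sum_j A_j e^{-ij\omega}|},
#' at `n_points` uniform frequencies \eqn{\omega_i = \pi i / F},
#' `i = 0..F-1` (covering `[0, Nyquist)`), in dB with a 1e-12 magnitude
#' floor.
#'
#' @param model An [lpc_model][levinson_durbin].
#' @param n_points Number of grid points F (>= 1).
#' @param rate Sampling rate in Hz (maps the grid to physical frequency).
#' @return An object of class `"spectral_envelope"`: list with `values`
#'   (dB magnitudes, length F) and `freq_grid` (Hz, length F).
#' @export
spectral_envelope <- function(model, n_points, rate = 44100) {
  stopifnot(inherits(model, "lpc_model"))
  n_points <- as.integer(n_points)
  if (n_points < 1L) stopf("'n_points' must be >= 1")
  den_poly <- c(1, model$denominator_coeffs)
  if (2L * n_points >= length(den_poly)) {
    den <- stats::fft(c(den_poly, numeric(2L * n_points - length(den_poly))))
    den <- Mod(den[seq_len(n_points)])
  } else {
    # grid shorter than the polynomial: evaluate directly
    om <- pi * (0:(n_points - 1L)) / n_points
    j <- seq_along(model$denominator_coeffs)
    den <- vapply(om, function(w)
      Mod(1 + sum(model$denominator_coeffs * exp(-1i * j * w))), 0)
  }
  mag <- pmax(model$gain / pmax(den, 1e-300), 1e-12)
  structure(
    list(values = 20 * log10(mag),
         freq_grid = (0:(n_points - 1L)) * rate / (2 * n_points)),
    class = "spectral_envelope")
}

#' LPC spectral-envelope feature vector of a clip
#'
#' The whole (standardized) clip is Hamming-windowed, its autocorrelation
#' computed to lag P, an order-P all-pole model fit by
#' [levinson_durbin], and the model's [spectral_envelope] sampled at
#' `n_points` frequencies. One clip and one prediction order therefore
#' yield exactly one length-`n_points` feature vector.
#'
#' @param clip An [audio_clip] (standardized).
#' @param order Prediction order P.
#' @param n_points Envelope grid length F (default 10240).
#' @return Numeric feature vector of length `n_points` (dB values).
#' @export
lpc_feature <- function(clip, order, n_points = 10240) {
  stopifnot(inherits(clip, "audio_clip"))
  r <- clip_autocorr(clip, max_lag = order)
  model <- levinson_durbin(r, order)
  spectral_envelope(model, n_points, clip$rate)$values
}

# Hamming-window the whole clip and autocorrelate; split out so a sweep
# over many orders can reuse one autocorrelation of each clip.
clip_autocorr <- function(clip, max_lag) {
  w <- as.numeric(signal::hamming(length(clip$samples)))
  autocorrelation(clip$samples * w, max_lag)
}
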
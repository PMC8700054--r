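#' MFCC extraction configuration
#'
#' Canonical settings for the mel-cepstral chain: 2048-sample frames with
#' a 1024-sample hop, a 26-filter mel bank spanning 0 Hz to Nyquist, 13
#' retained cepstra, and a flattened feature length of 10240.
#'
#' @param frame_len Frame length in samples.
#' @param hop_len Hop between frame starts in samples (<= `frame_len`).
#' @param n_mels Number of triangular mel filters.
#' @param n_cepstra Number of retained DCT coefficients (<= `n_mels`).
#' @param fmin,fmax Filterbank frequency range in Hz; `fmax = NULL` means
#'   the Nyquist frequency of the clip being processed.
#' @param target_len Flattened feature-vector length.
#' @return An object of class `"mfcc_config"`.
#' @export
mfcc_config <- function(frame_len = 2048, hop_len = 1024, n_mels = 26,
                        n_cepstra = 13, fmin = 0, fmax = NULL,
                        target_len = 10240) {
  frame_len <- as.integer(frame_len); hop_len <- as.integer(hop_len)
  if (hop_len < 1L || hop_len > frame_len)
    stopf("'hop_len' must be in 1..frame_len")
  if (n_cepstra > n_mels) stopf("'n_cepstra' must be <= 'n_mels'")
  if (fmin < 0) stopf("'fmin' must be >= 0")
  structure(
    list(frame_len = frame_len, hop_len = hop_len,
         n_mels = as.integer(n_mels), n_cepstra = as.integer(n_cepstra),
         fmin = fmin, fmax = fmax, target_len = as.integer(target_len)),
    class = "mfcc_config")
}

#' Pre-emphasis filter
#'
#' First-order high-pass `y[n] = x[n] - alpha * x[n-1]` (with
#' `y[1] = x[1]`), the filter whose coefficient is swept 0.22-1.00 to
#' generate feature diversity.
#'
#' @param x Numeric sample vector.
#' @param alpha Pre-emphasis coefficient in \[0, 1\].
#' @return Filtered vector, same length as `x`.
#' @export
pre_emphasis <- function(x, alpha) {
  if (alpha < 0 || alpha > 1) stopf("'alpha' must be in [0, 1]")
  if (length(x) < 2L) return(x)
  c(x[1], x[-1] - alpha * x[-length(x)])
}

#' Hz to mel and back
#'
#' The standard perceptual mel scale
#' \eqn{mel(f) = 2595 \log_{10}(1 + f/700)}.
#'
#' @param f Frequency in Hz.
#' @param m Frequency in mel.
#' @return Converted value(s).
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' `n_mels` triangular filters with mel-equispaced centers between `fmin`
#' and `fmax`, sampled at the `n_fft/2 + 1` non-negative FFT bin
#' frequencies.
#'
#' @param n_mels Number of filters.
#' @param n_fft FFT length the filters are applied to.
#' @param rate Sampling rate in Hz.
#' @param fmin,fmax Frequency range in Hz.
#' @return `n_mels x (n_fft/2 + 1)` non-negative weight matrix.
#' @export
mel_filterbank <- function(n_mels, n_fft, rate, fmin = 0, fmax = rate / 2) {
  if (fmax > rate / 2 + 1e-9) stopf("'fmax' must be <= rate/2")
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (0:(n_bins - 1L)) * rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                         length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal type-II DCT matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1L)
  n <- 0:(n_in - 1L)
  C <- sqrt(2 / n_in) * cos(pi * outer(k, n + 0.5) / n_in)
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' Frame-wise MFCC matrix of a clip
#'
#' Per frame: Hamming window, magnitude-squared FFT, triangular mel
#' filterbank energies, natural log with a 1e-12 floor, orthonormal
#' type-II DCT keeping the first `n_cepstra` coefficients. Pre-emphasis
#' is *not* applied here; see [mfcc_feature].
#'
#' @param clip An [audio_clip] at least one frame long.
#' @param config An [mfcc_config].
#' @return An object of class `"mfcc_matrix"`: list with `coeffs`
#'   (`n_frames x n_cepstra`) and `config`.
#' @export
mfcc_matrix <- function(clip, config = mfcc_config()) {
  stopifnot(inherits(clip, "audio_clip"), inherits(config, "mfcc_config"))
  x <- clip$samples
  fl <- config$frame_len; hl <- config$hop_len
  if (length(x) < fl)
    stopf("clip has %d samples, shorter than one %d-sample frame",
          length(x), fl)
  n_frames <- 1L + (length(x) - fl) %/% hl
  idx <- outer(seq_len(fl), (seq_len(n_frames) - 1L) * hl, "+")
  frames <- matrix(x[idx], nrow = fl) * as.numeric(signal::hamming(fl))
  spec <- stats::mvfft(frames)
  power <- Mod(spec[seq_len(fl %/% 2L + 1L), , drop = FALSE])^2
  fmax <- if (is.null(config$fmax)) clip$rate / 2 else config$fmax
  fb <- mel_filterbank(config$n_mels, fl, clip$rate, config$fmin, fmax)
  loge <- log(pmax(fb %*% power, 1e-12))
  cep <- dct_matrix(config$n_cepstra, config$n_mels) %*% loge
  structure(list(coeffs = t(cep), config = config), class = "mfcc_matrix")
}

#' Pre-emphasis-swept MFCC feature vector of a clip
#'
#' Applies [pre_emphasis] with coefficient `alpha`, computes the
#' frame-wise [mfcc_matrix], flattens it time-major (frame 1's cepstra
#' first), and truncates (or zero-pads) to `config$target_len`.
#'
#' @param clip An [audio_clip] (standardized).
#' @param alpha Pre-emphasis coefficient in \[0, 1\].
#' @param config An [mfcc_config].
#' @return Numeric feature vector of length `config$target_len`.
#' @export
mfcc_feature <- function(clip, alpha, config = mfcc_config()) {
  emph <- audio_clip(pre_emphasis(clip$samples, alpha), clip$rate,
                     clip$species_index, clip$clip_id)
  cep <- mfcc_matrix(emph, config)$coeffs
  flat <- as.vector(t(cep))  # frame-major
  tl <- config$target_len
  if (length(flat) >= tl) flat[seq_len(tl)]
  else c(flat, numeric(tl - length(flat)))
}
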
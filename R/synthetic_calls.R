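#' Specify a synthetic species voice
#'
#' A `species_spec` parameterizes one synthetic anuran "voice": a harmonic
#' stack with per-harmonic amplitude decay, gated by a pulse train (the
#' call rhythm), with slow sinusoidal frequency modulation and additive
#' white Gaussian noise at a prescribed signal-to-noise ratio.
#'
#' @param species_index Integer label (1-based).
#' @param fundamental_hz Fundamental frequency in Hz.
#' @param n_harmonics Number of harmonics (>= 1); the highest harmonic
#'   must stay below the Nyquist frequency of `rate`.
#' @param harmonic_decay Per-harmonic amplitude ratio in (0, 1].
#' @param pulse_rate_hz Amplitude-gate pulse rate in Hz (>= 0; 0 = tonal,
#'   no gating).
#' @param pulse_duty Fraction of each pulse period that is "on", in (0, 1].
#' @param fm_depth_hz Peak deviation of the slow frequency modulation, Hz.
#' @param snr_db Signal-to-noise ratio of the added white noise, in dB
#'   (`Inf` disables noise).
#' @param rate Sampling rate (Hz) the aliasing check is made against.
#' @return An object of class `"species_spec"`.
#' @export
species_spec <- function(species_index, fundamental_hz, n_harmonics = 4,
                         harmonic_decay = 0.7, pulse_rate_hz = 8,
                         pulse_duty = 0.5, fm_depth_hz = 0, snr_db = 15,
                         rate = 44100) {
  check_scalar_num(fundamental_hz, "fundamental_hz", positive = TRUE)
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stopf("'n_harmonics' must be >= 1")
  if (fundamental_hz * n_harmonics >= rate / 2)
    stopf("highest harmonic (%g Hz) reaches Nyquist (%g Hz): aliasing",
          fundamental_hz * n_harmonics, rate / 2)
  if (harmonic_decay <= 0 || harmonic_decay > 1)
    stopf("'harmonic_decay' must be in (0, 1]")
  if (pulse_rate_hz < 0) stopf("'pulse_rate_hz' must be >= 0")
  if (pulse_duty <= 0 || pulse_duty > 1)
    stopf("'pulse_duty' must be in (0, 1]")
  structure(
    list(species_index = as.integer(species_index),
         fundamental_hz = fundamental_hz, n_harmonics = n_harmonics,
         harmonic_decay = harmonic_decay, pulse_rate_hz = pulse_rate_hz,
         pulse_duty = pulse_duty, fm_depth_hz = fm_depth_hz,
         snr_db = snr_db),
    class = "species_spec")
}

#' Generate a separable grid of synthetic species voices
#'
#' Spreads fundamentals log-uniformly over 400-6000 Hz with a seeded
#' jitter while guaranteeing that adjacent fundamentals differ by at
#' least 5%, so the classes are separable by spectral envelope. The
#' remaining voice parameters (harmonic count and decay, pulse rate and
#' duty cycle, FM depth) are drawn from ranges typical of anuran
#' advertisement calls; noise defaults to a 15 dB SNR.
#'
#' @param n_species Number of species (>= 2). The 5% separation
#'   constraint over 400-6000 Hz admits at most 56 species.
#' @param seed Integer seed; the grid is deterministic in it.
#' @param rate Sampling rate in Hz used for the aliasing cap.
#' @return A list of `n_species` [species_spec] objects, ordered by
#'   ascending fundamental.
#' @export
make_species_grid <- function(n_species = 35, seed = 0, rate = 44100) {
  n_species <- as.integer(n_species)
  if (n_species < 2L) stopf("'n_species' must be >= 2")
  # upper fundamental stays clear of Nyquist at low sampling rates
  lo <- log(400); hi <- log(min(6000, 0.4 * rate))
  if (hi <= lo) stopf("sampling rate %g Hz is too low for the 400 Hz fundamental floor", rate)
  gap <- (hi - lo) / (n_species - 1)
  min_gap <- log(1.05)
  if (gap < min_gap)
    stopf("%d species cannot keep adjacent fundamentals >= 5%% apart in 400-6000 Hz (max 56)",
          n_species)
  with_seed(seed, {
    jit <- stats::runif(n_species, -1, 1) * pmax(0, (gap - min_gap) / 2) * 0.9
    # clamp to the band so endpoint jitter cannot cross Nyquist; the
    # jitter bound keeps adjacent log-gaps >= min_gap even after clamping
    pos <- pmin(pmax(lo + gap * (seq_len(n_species) - 1) + jit, lo), hi)
    fund <- exp(pos)
    lapply(seq_len(n_species), function(s) {
      h_cap <- max(1L, min(8L, floor((rate / 2 - 1) / fund[s])))
      species_spec(
        species_index = s,
        fundamental_hz = fund[s],
        n_harmonics = if (h_cap >= 3L) sample(3:h_cap, 1L) else h_cap,
        harmonic_decay = stats::runif(1, 0.5, 0.9),
        pulse_rate_hz = stats::runif(1, 2, 15),
        pulse_duty = stats::runif(1, 0.3, 0.8),
        fm_depth_hz = stats::runif(1, 0, 30),
        snr_db = 15,
        rate = rate)
    })
  })
}

#' Synthesize one call from a species voice
#'
#' Builds the harmonic pulse-train
#' \deqn{x(t) = g(t) \sum_{h=1}^{H} d^{h-1} \sin(2\pi h \phi(t))}
#' where \eqn{\phi'(t)} is the FM-modulated fundamental, `g(t)` a square
#' pulse gate at `pulse_rate_hz` with duty `pulse_duty`, plus white
#' Gaussian noise scaled so the realized clip SNR equals `snr_db`
#' exactly. Fully deterministic in `seed`.
#'
#' @param spec A [species_spec].
#' @param rate Sampling rate in Hz.
#' @param duration Clip duration in seconds.
#' @param seed Integer seed for phases, gate offset and noise.
#' @param clip_id Identifier for the resulting clip.
#' @return An [audio_clip] labelled with `spec$species_index`.
#' @export
synthesize_call <- function(spec, rate = 44100, duration = 20, seed = 0,
                            clip_id = NULL) {
  stopifnot(inherits(spec, "species_spec"))
  check_scalar_num(duration, "duration", positive = TRUE)
  n <- round(rate * duration)
  t <- (0:(n - 1)) / rate
  with_seed(seed, {
    fm_rate <- 3  # Hz, slow vibrato
    phase0 <- stats::runif(spec$n_harmonics, 0, 2 * pi)
    gate_off <- stats::runif(1)
    # integral of (fundamental + fm_depth * sin(2 pi fm_rate t)) dt
    phi <- spec$fundamental_hz * t +
      spec$fm_depth_hz * (1 - cos(2 * pi * fm_rate * t)) / (2 * pi * fm_rate)
    sig <- numeric(n)
    for (h in seq_len(spec$n_harmonics))
      sig <- sig + spec$harmonic_decay^(h - 1) *
        sin(2 * pi * h * phi + phase0[h])
    if (spec$pulse_rate_hz > 0 && spec$pulse_duty < 1) {
      gate <- as.numeric(((t * spec$pulse_rate_hz + gate_off) %% 1) <
                           spec$pulse_duty)
      sig <- sig * gate
    }
    if (is.finite(spec$snr_db)) {
      w <- stats::rnorm(n)
      w <- w / sqrt(mean(w^2))
      sig_p <- mean(sig^2)
      noise <- w * sqrt(sig_p) * 10^(-spec$snr_db / 20)
      sig <- sig + noise
    }
    if (is.null(clip_id))
      clip_id <- sprintf("sp%02d_seed%d", spec$species_index, seed)
    audio_clip(sig, rate, spec$species_index, clip_id)
  })
}

#' Generate a labelled synthetic corpus
#'
#' One deterministic grid of species voices (see [make_species_grid]) and
#' `clips_per_species` seeded realizations of each; the defaults emulate
#' a 35-class corpus of 20-second, 44100 Hz call recordings with one
#' source clip per species.
#'
#' @param n_species Number of species (>= 2).
#' @param clips_per_species Clips per species (>= 1). Values > 1 give
#'   leakage-free group-aware evaluation a chance (see [split_dataset]).
#' @param rate Sampling rate in Hz.
#' @param duration Clip duration in seconds.
#' @param seed Integer master seed; everything derives from it.
#' @return A list of `n_species * clips_per_species` [audio_clip]s,
#'   species-major.
#' @export
generate_corpus <- function(n_species = 35, clips_per_species = 1,
                            rate = 44100, duration = 20, seed = 0) {
  clips_per_species <- as.integer(clips_per_species)
  if (clips_per_species < 1L) stopf("'clips_per_species' must be >= 1")
  grid <- make_species_grid(n_species, seed = seed, rate = rate)
  out <- vector("list", n_species * clips_per_species)
  k <- 0L
  for (s in seq_len(n_species)) {
    for (cpt in seq_len(clips_per_species)) {
      k <- k + 1L
      out[[k]] <- synthesize_call(
        grid[[s]], rate = rate, duration = duration,
        seed = derive_seed(seed, s, cpt),
        clip_id = sprintf("sp%02d_c%d", s, cpt))
    }
  }
  out
}

#' Write a corpus to WAV files plus a manifest
#'
#' @param corpus List of [audio_clip] objects.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(corpus, function(clip) {
    fn <- paste0(clip$clip_id, ".wav")
    # scale into [-1, 1] for 16-bit storage; peak level is restored by
    # standardize() downstream anyway
    peak <- max(abs(clip$samples))
    scl <- clip
    if (peak > 1) scl$samples <- clip$samples / peak
    write_wav_clip(scl, file.path(dir, fn))
    data.frame(path = fn, species_index = clip$species_index,
               species_name = sprintf("species_%02d", clip$species_index),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}
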
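#' Construct a labelled mono audio clip
#'
#' `audio_clip` is the canonical unit of raw input for the pipeline: a
#' finite mono waveform, its sampling rate, and the species label of the
#' animal that produced it.
#'
#' @param samples Numeric vector of dimensionless amplitudes.
#' @param rate Sampling frequency in Hz (> 0).
#' @param species_index Integer species label (1-based), or `NA` when the
#'   clip is unlabelled.
#' @param clip_id Opaque identifier string; defaults to `"clip"`.
#' @return An object of class `"audio_clip"`: a list with elements
#'   `samples`, `rate`, `species_index`, `clip_id`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * (0:999) / 8000), 8000, 1)
#' clip$rate
#' @export
audio_clip <- function(samples, rate, species_index = NA_integer_,
                       clip_id = "clip") {
  if (!is.numeric(samples) || length(samples) < 1L)
    stopf("'samples' must be a non-empty numeric vector")
  if (any(!is.finite(samples)))
    stopf("'samples' contains non-finite values (NaN/Inf)")
  check_scalar_num(rate, "rate", positive = TRUE)
  if (!is.na(species_index)) {
    species_index <- as.integer(species_index)
    if (species_index < 1L) stopf("'species_index' must be >= 1")
  }
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         species_index = species_index, clip_id = as.character(clip_id)),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip '%s'> %d samples @ %g Hz (%.2f s), species %s\n",
              x$clip_id, length(x$samples), x$rate,
              length(x$samples) / x$rate,
              ifelse(is.na(x$species_index), "NA", x$species_index)))
  invisible(x)
}

#' Read a WAV file as a labelled mono clip
#'
#' Parses RIFF/WAVE containers holding integer PCM (8/16/24/32 bit) or
#' IEEE float (32/64 bit) data. Multi-channel audio is averaged to mono.
#'
#' @param path Path to a readable WAV file.
#' @param species_index Integer species label to attach (optional).
#' @return An [audio_clip] at the file's native sample rate, with samples
#'   scaled to `[-1, 1]` for integer PCM.
#' @export
read_wav_clip <- function(path, species_index = NA_integer_) {
  if (!file.exists(path)) stopf("cannot read WAV file: '%s'", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 44 || rawToChar(raw[1:4]) != "RIFF" ||
      rawToChar(raw[9:12]) != "WAVE")
    stopf("'%s' is not a RIFF/WAVE file", path)

  pos <- 13L
  fmt <- NULL
  data <- NULL
  while (pos + 8L <= length(raw)) {
    id <- rawToChar(raw[pos:(pos + 3L)])
    sz <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4,
                  endian = "little")
    body_start <- pos + 8L
    body_end <- min(body_start + sz - 1L, length(raw))
    if (id == "fmt ") {
      b <- raw[body_start:body_end]
      fmt <- list(
        code = readBin(b[1:2], "integer", size = 2, endian = "little",
                       signed = FALSE),
        channels = readBin(b[3:4], "integer", size = 2, endian = "little"),
        rate = readBin(b[5:8], "integer", size = 4, endian = "little"),
        bits = readBin(b[15:16], "integer", size = 2, endian = "little"))
    } else if (id == "data") {
      data <- raw[body_start:body_end]
    }
    pos <- body_start + sz + (sz %% 2L)  # chunks are word-aligned
  }
  if (is.null(fmt) || is.null(data))
    stopf("'%s' is missing its fmt/data chunk", path)

  x <- decode_wav_samples(data, fmt, path)
  if (length(x) == 0L) stopf("'%s' contains no audio samples", path)
  if (fmt$channels > 1L) {
    n <- (length(x) %/% fmt$channels) * fmt$channels
    x <- colMeans(matrix(x[seq_len(n)], nrow = fmt$channels))
  }
  audio_clip(x, fmt$rate, species_index,
             clip_id = sub("\\.[Ww][Aa][Vv]$", "", basename(path)))
}

# Decode the raw data chunk of a WAV file to doubles in [-1, 1].
decode_wav_samples <- function(data, fmt, path) {
  n_bytes <- fmt$bits %/% 8L
  n <- length(data) %/% n_bytes
  if (fmt$code == 1L || fmt$code == 65534L) {  # integer PCM
    if (fmt$bits == 8L) {
      as.integer(data[seq_len(n)]) / 127.5 - 1
    } else if (fmt$bits == 16L) {
      # symmetric scale matching the writer, so round-trips are tight
      readBin(data, "integer", n = n, size = 2, endian = "little") / 32767
    } else if (fmt$bits == 24L) {
      b <- as.integer(data[seq_len(n * 3L)])
      v <- b[seq(1, by = 3, length.out = n)] +
        256 * b[seq(2, by = 3, length.out = n)] +
        65536 * b[seq(3, by = 3, length.out = n)]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    } else if (fmt$bits == 32L) {
      readBin(data, "integer", n = n, size = 4, endian = "little") / 2147483648
    } else stopf("unsupported PCM bit depth %d in '%s'", fmt$bits, path)
  } else if (fmt$code == 3L) {  # IEEE float
    readBin(data, "double", n = n, size = n_bytes, endian = "little")
  } else stopf("unsupported WAV format code %d in '%s'", fmt$code, path)
}

#' Write a mono clip to a 16-bit PCM WAV file
#'
#' @param clip An [audio_clip].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav_clip <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(pmax(clip$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  rate <- as.integer(round(clip$rate))
  data_sz <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Standardize a clip to a canonical rate, duration and level
#'
#' Resamples (band-limited, polyphase FIR via [signal::resample]) to
#' `target_rate` when needed, truncates or zero-pads to exactly
#' `round(target_rate * target_duration)` samples, and peak-normalizes to
#' `max |sample| = 1`. All-zero clips are passed through in amplitude with
#' a warning.
#'
#' The canonical defaults (44100 Hz, 20 s) match the corpus convention of
#' whole ~20-second call recordings.
#'
#' @param clip An [audio_clip].
#' @param target_rate Target sampling rate in Hz.
#' @param target_duration Target duration in seconds.
#' @return A standardized [audio_clip].
#' @export
standardize <- function(clip, target_rate = 44100, target_duration = 20) {
  stopifnot(inherits(clip, "audio_clip"))
  check_scalar_num(target_rate, "target_rate", positive = TRUE)
  check_scalar_num(target_duration, "target_duration", positive = TRUE)
  x <- clip$samples
  if (clip$rate != target_rate) {
    p <- as.integer(round(target_rate))
    q <- as.integer(round(clip$rate))
    g <- gcd_int(p, q)
    x <- as.numeric(signal::resample(x, p %/% g, q %/% g))
  }
  n_target <- round(target_rate * target_duration)
  if (length(x) >= n_target) x <- x[seq_len(n_target)]
  else x <- c(x, numeric(n_target - length(x)))
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  else warning(sprintf("clip '%s' is all-zero; amplitude left unchanged",
                       clip$clip_id))
  audio_clip(x, target_rate, clip$species_index, clip$clip_id)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Read a corpus manifest
#'
#' A manifest is a CSV with columns `path`, `species_index`,
#' `species_name`; `path` is interpreted relative to the manifest's
#' directory unless absolute.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list of [audio_clip] objects in manifest order.
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stopf("cannot read manifest: '%s'", manifest_path)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "species_index")
  if (!all(need %in% names(m)))
    stopf("manifest must have columns 'path' and 'species_index'")
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(m)), function(i) {
    p <- m$path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    read_wav_clip(p, m$species_index[i])
  })
}
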
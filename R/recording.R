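#' Fixed-length mono audio recording
#'
#' Container for one acquired (or synthesised) breathing-pattern window:
#' mono samples in `[-1, 1]`, the sample rate, and the duration of the
#' leading silence used downstream for noise estimation.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in Hz (default 22050).
#' @param silence_lead_s Leading silence duration in seconds (default 1);
#'   must be shorter than the recording.
#' @return An object of class `raw_recording` with fields `samples`,
#'   `sample_rate_hz`, `duration_s`, `silence_lead_s`.
#' @export
raw_recording <- function(samples, sample_rate_hz = 22050, silence_lead_s = 1) {
  if (!is.numeric(samples) || length(samples) < 1L || anyNA(samples)) {
    stop_bpi("invalid_argument", "`samples` must be a non-empty numeric vector")
  }
  check_scalar_number(sample_rate_hz, "sample_rate_hz")
  check_scalar_number(silence_lead_s, "silence_lead_s")
  if (max(abs(samples)) > 1 + 1e-9) {
    stop_bpi("invalid_argument", "sample amplitudes must lie in [-1, 1]")
  }
  duration_s <- length(samples) / sample_rate_hz
  if (silence_lead_s >= duration_s) {
    stop_bpi("invalid_argument",
             "silence_lead_s (%g s) must be shorter than the recording (%g s)",
             silence_lead_s, duration_s)
  }
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = sample_rate_hz,
         duration_s = duration_s,
         silence_lead_s = silence_lead_s),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples @ %g Hz (%.3f s, %.2f s lead silence)\n",
              length(x$samples), x$sample_rate_hz, x$duration_s,
              x$silence_lead_s))
  invisible(x)
}

#' Write a recording as a 16-bit PCM mono WAV file
#'
#' @param rec A [raw_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  s <- pmax(pmin(rec$samples, 1), -1)
  pcm <- as.integer(round(s * 32767))
  data_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")     # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(as.integer(rec$sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate_hz) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @param silence_lead_s Leading-silence annotation to attach (default 1 s).
#' @return A [raw_recording()].
#' @export
read_wav <- function(path, silence_lead_s = 1) {
  if (!file.exists(path)) {
    stop_bpi("io_error", "cannot read WAV file: %s", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_bpi("io_error", "not a RIFF/WAVE file: %s", path)
  }
  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")  # byte rate
      readBin(con, "integer", size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L || bits != 16L) {
        stop_bpi("io_error",
                 "unsupported WAV format in %s (need 16-bit PCM mono)", path)
      }
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", n = size %/% 2L, size = 2,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", n = size)
    }
  }
  if (is.null(sample_rate) || is.null(samples)) {
    stop_bpi("io_error", "malformed WAV file (missing fmt/data chunk): %s", path)
  }
  raw_recording(samples / 32767, sample_rate_hz = sample_rate,
                silence_lead_s = silence_lead_s)
}

#' Measure signal-to-noise ratio against a known clean component
#'
#' Projects the observed signal onto the clean reference (compensating for
#' any overall gain applied by processing) and reports
#' `10 log10(a^2 * sum(clean^2) / sum(residual^2))` where `a` is the fitted
#' gain and `residual = observed - a * clean`.
#'
#' @param clean Numeric vector, the known clean component.
#' @param observed Numeric vector of the same length.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, observed) {
  if (length(clean) != length(observed)) {
    stop_bpi("shape_error", "clean and observed signals must have equal length")
  }
  pc <- sum(clean^2)
  if (pc <= 0) stop_bpi("invalid_argument", "clean reference has zero power")
  a <- sum(clean * observed) / pc
  resid <- observed - a * clean
  pr <- sum(resid^2)
  if (pr <= 0) return(Inf)
  10 * log10(a^2 * pc / pr)
}
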
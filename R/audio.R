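#' Construct a mono audio signal
#'
#' Container for a sampled waveform: amplitudes (dimensionless, nominally in
#' `[-1, 1]`) plus the sampling rate in Hz. The reference rate of the CPP
#' configuration defaults is 16,000 Hz.
#'
#' @param samples numeric vector of amplitudes (single channel).
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop_input("samples must be a non-empty numeric vector")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop_input("rate must be a single positive number (Hz)")
  }
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

# --- minimal RIFF/WAVE codec ------------------------------------------------
# Mono PCM 16-bit (format tag 1) and IEEE float32 (format tag 3) only; the
# installed stack has no WAV reader, and the pipeline needs nothing more.

#' Read a mono WAV file
#'
#' Supports uncompressed PCM 16-bit and IEEE float 32-bit, single channel.
#' Multi-channel files are rejected: downmix externally before extraction.
#'
#' @param path path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_input("WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_input("not a RIFF/WAVE file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")  # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_input("not a RIFF/WAVE file: %s", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        tag      = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2L))  # skip unknown chunk (+pad)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_input("malformed WAV (missing fmt/data chunk): %s", path)
  }
  if (fmt$channels != 1L) {
    stop_input("%s has %d channels; only mono input is supported - downmix first",
               path, fmt$channels)
  }
  samples <- if (fmt$tag == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$tag == 3L && fmt$bits == 32L) {
    readBin(data_raw, "numeric", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop_input("unsupported WAV encoding (format tag %d, %d bit) in %s",
               fmt$tag, fmt$bits, path)
  }
  audio_signal(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param signal an [audio_signal()].
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!bits %in% c(16, 32)) stop_input("bits must be 16 (PCM) or 32 (float)")
  n <- length(signal$samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(signal$rate), con, 4, endian = "little")
  writeBin(as.integer(signal$rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    q <- pmax(pmin(round(signal$samples * 32768), 32767), -32768)
    writeBin(as.integer(q), con, 2, endian = "little")
  } else {
    writeBin(signal$samples, con, 4, endian = "little")
  }
  invisible(path)
}
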
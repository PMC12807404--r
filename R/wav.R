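#' Waveform objects
#'
#' A waveform is a light container for audio samples: a numeric vector (mono)
#' or a samples-by-channels matrix, plus a sampling rate in Hz. Sample values
#' are real-valued; PCM files are scaled to [-1, 1] on read.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param rate_hz Sampling rate in samples per second.
#' @return An object of class `waveform`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 16000)), 16000)
#' wave_duration(w)
waveform <- function(samples, rate_hz) {
  if (!is.numeric(samples)) abort("`samples` must be numeric")
  if (!is_scalar_number(rate_hz) || rate_hz <= 0) abort("`rate_hz` must be a positive number")
  structure(list(samples = samples, rate_hz = rate_hz), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  nch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  cat(sprintf("<waveform: %.3f s, %d Hz, %d channel(s)>\n",
              wave_duration(x), x$rate_hz, nch))
  invisible(x)
}

#' @rdname waveform
#' @param w A `waveform`.
#' @export
wave_duration <- function(w) {
  n <- if (is.matrix(w$samples)) nrow(w$samples) else length(w$samples)
  n / w$rate_hz
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 8/16/32-bit PCM, the format the
#' toy audio generator writes and interview recordings are distributed in.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(paste0("WAV file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(paste0("Not a RIFF file: ", path))
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(paste0("Not a WAVE file: ", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, size = 2, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort(paste0("Malformed WAV (missing fmt/data chunk): ", path))
  if (fmt$audio_format != 1L) abort("Only uncompressed PCM WAV is supported")

  bytes <- fmt$bits / 8
  n_total <- length(data_raw) %/% bytes
  vals <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n_total, size = 1, signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer", n_total, size = 2, endian = "little")) / 32768,
    "32" = as.numeric(readBin(data_raw, "integer", n_total, size = 4, endian = "little")) / 2147483648,
    abort(paste0("Unsupported PCM bit depth: ", fmt$bits))
  )
  if (fmt$n_channels > 1L) {
    vals <- matrix(vals, ncol = fmt$n_channels, byrow = TRUE)
  }
  waveform(vals, fmt$sample_rate)
}

#' Write a PCM WAV file
#'
#' @param w A [waveform()]; samples are clipped to `[-1, 1]`.
#' @param path Output path.
#' @param bits Bit depth (16 only).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16) {
  stopifnot(inherits(w, "waveform"), bits == 16)
  samp <- w$samples
  if (is.matrix(samp)) {
    n_channels <- ncol(samp)
    interleaved <- as.numeric(t(samp))
  } else {
    n_channels <- 1L
    interleaved <- as.numeric(samp)
  }
  pcm <- as.integer(pmax(-32768, pmin(32767, round(pmax(-1, pmin(1, interleaved)) * 32767))))
  byte_rate <- w$rate_hz * n_channels * 2L
  data_size <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(as.integer(n_channels), con, size = 2, endian = "little")
  writeBin(as.integer(w$rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(n_channels * 2L), con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
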
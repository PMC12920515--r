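# Minimal mono WAV (RIFF) I/O: PCM 16/24-bit and IEEE float32.

#' Audio waveform container
#'
#' A sampled pressure signal with its sample rate. Samples are stored as
#' doubles in arbitrary units (PCM files are scaled to \[-1, 1\] on read).
#'
#' @param samples numeric vector of finite sample values.
#' @param sample_rate sampling rate in Hz (positive).
#' @return an object of class `audio_wave` with fields `samples` and
#'   `sample_rate`.
#' @export
audio_wave <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("audio samples must be finite")
  }
  sample_rate <- as.integer(sample_rate)
  if (length(sample_rate) != 1L || is.na(sample_rate) || sample_rate <= 0L) {
    stop("sample_rate must be a positive scalar")
  }
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "audio_wave")
}

#' @export
print.audio_wave <- function(x, ...) {
  cat(sprintf("<audio_wave> %d samples @ %d Hz (%.3f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Read a mono WAV file
#'
#' Supports uncompressed PCM (16- or 24-bit) and IEEE float32 mono files.
#' Multichannel files are rejected. Integer PCM is scaled to \[-1, 1\].
#'
#' @param path path to a `.wav` file.
#' @return an [audio_wave()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate     = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (fmt$channels != 1L) {
    stop("only mono WAV is supported (file has ", fmt$channels, " channels)")
  }
  samples <- decode_wav_samples(data_raw, fmt$format, fmt$bits)
  audio_wave(samples, fmt$rate)
}

decode_wav_samples <- function(raw, format, bits) {
  if (format == 1L && bits == 16L) {
    readBin(raw, "integer", length(raw) / 2, size = 2,
            endian = "little", signed = TRUE) / 32768
  } else if (format == 1L && bits == 24L) {
    n <- length(raw) / 3
    m <- matrix(as.integer(raw), nrow = 3)
    v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v[seq_len(n)] / 8388608
  } else if (format == 3L && bits == 32L) {
    readBin(raw, "double", length(raw) / 4, size = 4, endian = "little")
  } else {
    stop("unsupported WAV encoding: format tag ", format, ", ", bits, " bits")
  }
}

#' Write a mono WAV file
#'
#' @param wave an [audio_wave()].
#' @param path output path.
#' @param bit_depth `"16"`, `"24"` (PCM, input clipped to \[-1, 1\]) or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bit_depth = c("16", "24", "float32")) {
  bit_depth <- match.arg(bit_depth)
  stopifnot(inherits(wave, "audio_wave"))
  x <- wave$samples
  if (bit_depth %in% c("16", "24")) x <- pmin(1, pmax(-1, x))
  payload <- switch(bit_depth,
    "16" = writeBin(pmin(as.integer(round(x * 32768)), 32767L), raw(),
                    size = 2, endian = "little"),
    "24" = {
      v <- pmin(as.integer(round(x * 8388608)), 8388607L)
      v <- ifelse(v < 0, v + 16777216L, v)
      as.raw(rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L))
    },
    "float32" = writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  )
  fmt_tag <- if (bit_depth == "float32") 3L else 1L
  bits <- switch(bit_depth, "16" = 16L, "24" = 24L, "float32" = 32L)
  block <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(payload)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(wave$sample_rate, con, size = 4, endian = "little")
  writeBin(wave$sample_rate * block, con, size = 4, endian = "little")
  writeBin(block, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}
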
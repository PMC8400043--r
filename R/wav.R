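#' Construct a sound recording
#'
#' A `sound_recording` holds a mono sequence of sound-pressure samples at a
#' fixed sample rate. Samples are interpreted in pascals, so a 1 Pa RMS signal
#' is 94 dB SPL; recordings in arbitrary digital units carry a
#' `calibration_offset` in dB that is added to every computed level.
#'
#' @param samples Numeric vector of finite sound-pressure samples (Pa, or
#'   digital units together with `calibration_offset`).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param calibration_offset dB added to computed sound-pressure levels to map
#'   digital full scale onto dB SPL re 20 µPa. Default 0 (samples already Pa).
#' @return An object of class `sound_recording`.
#' @export
sound_recording <- function(samples, sample_rate, calibration_offset = 0) {
  if (!is.numeric(samples) || length(samples) < 1L || !all(is.finite(samples))) {
    abort_invalid("`samples` must be a non-empty finite numeric vector (mono)")
  }
  assert_scalar_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  assert_scalar_number(calibration_offset, "calibration_offset")
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         calibration_offset = as.numeric(calibration_offset)),
    class = "sound_recording"
  )
}

#' @export
print.sound_recording <- function(x, ...) {
  cat(sprintf("<sound_recording: %d samples @ %g Hz (%.3f s), cal offset %g dB>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$calibration_offset))
  invisible(x)
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for mono PCM (16- or 24-bit) and IEEE float32
#' files. Integer samples are scaled to [-1, 1) full scale.
#'
#' @param path Path to a WAV file.
#' @param calibration_offset dB offset stored on the returned recording.
#' @return A [sound_recording()].
#' @export
read_wav <- function(path, calibration_offset = 0) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort_invalid("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort_invalid("not a WAVE file")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      chunk <- readBin(con, "raw", size)
      hdr <- function(off, n) sum(as.integer(chunk[off + seq_len(n)]) * 256^(seq_len(n) - 1))
      fmt <- list(
        audio_format = hdr(0, 2), channels = hdr(2, 2),
        sample_rate = hdr(4, 4), bits = hdr(14, 2)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort_invalid("malformed WAV: missing fmt/data chunk")
  if (fmt$channels != 1L) abort_invalid("only mono WAV files are supported")

  samples <- if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "numeric", n = length(data_raw) / 4L, size = 4,
            endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n = length(data_raw) / 2L, size = 2,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else {
    abort_invalid(sprintf("unsupported WAV encoding (format %d, %d bit)",
                          fmt$audio_format, fmt$bits))
  }
  sound_recording(samples, fmt$sample_rate, calibration_offset)
}

#' Write a mono WAV file
#'
#' @param rec A [sound_recording()].
#' @param path Output path.
#' @param bits 32 (IEEE float, default: preserves pascal-valued samples
#'   exactly) or 16 (PCM; samples are clipped to [-1, 1)).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 32) {
  stopifnot(inherits(rec, "sound_recording"))
  if (!bits %in% c(16, 32)) abort_invalid("`bits` must be 16 or 32")
  x <- rec$samples
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3L else 1L), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  sr <- as.integer(round(rec$sample_rate))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    xi <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    writeBin(xi, con, size = 2, endian = "little")
  }
  invisible(path)
}
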
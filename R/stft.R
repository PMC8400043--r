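#' Periodic Hanning window
#'
#' The standard periodic Hann taper \eqn{w(n) = 0.5[1 - \cos(2\pi n/m)]},
#' \eqn{n = 0, \dots, m-1}, used before each short-time Fourier frame to
#' reduce spectral leakage.
#'
#' @param m Window length in samples (>= 2).
#' @return Numeric vector of length `m`, nonnegative, maximum 1.
#' @export
hanning_window <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 2) {
    abort_invalid("window length `m` must be a single number >= 2")
  }
  m <- as.integer(m)
  n <- seq_len(m) - 1L
  0.5 * (1 - cos(2 * pi * n / m))
}

#' Short-time Fourier transform of a voiding recording
#'
#' Computes a one-sided complex spectrogram with the conventions used
#' throughout the package: frames start every `hop = window_length *
#' (1 - overlap)` samples, each frame is tapered (Hanning by default) and
#' zero-padded to `fft_size`, frame times are stamped at the window centre,
#' and per-bin levels are expressed in dB SPL re 20 µPa using the recording's
#' calibration offset. With the default analysis settings (`fft_size = 4096`,
#' 25% overlap) the hop is 3072 samples.
#'
#' @param rec A [sound_recording()].
#' @param fft_size FFT length in samples (default 4096).
#' @param window_length Analysis window length in samples (default `fft_size`;
#'   must not exceed it).
#' @param overlap Fractional overlap of consecutive windows in `[0, 1)`
#'   (default 0.25).
#' @param window `"hanning"` (default) or `"rectangular"`.
#' @return An object of class `uroflow_stft` with elements `values` (complex
#'   matrix, bins x frames), `level_db` (same shape), `bin_freqs` (Hz),
#'   `frame_times` (s), plus the analysis settings.
#' @export
stft <- function(rec, fft_size = 4096, window_length = fft_size,
                 overlap = 0.25, window = c("hanning", "rectangular")) {
  stopifnot(inherits(rec, "sound_recording"))
  window <- match.arg(window)
  assert_scalar_number(fft_size, "fft_size", lower = 2)
  assert_scalar_number(window_length, "window_length", lower = 2,
                       upper = fft_size)
  assert_scalar_number(overlap, "overlap", lower = 0, upper = 1 - 1e-12)
  m <- as.integer(window_length)
  nfft <- as.integer(fft_size)
  x <- rec$samples
  if (length(x) < m) {
    abort_invalid("recording is shorter than one analysis window")
  }
  hop <- max(1L, as.integer(round(m * (1 - overlap))))
  n_frames <- (length(x) - m) %/% hop + 1L
  w <- if (window == "hanning") hanning_window(m) else rep(1, m)

  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(0, nrow = nfft, ncol = n_frames)
  for (j in seq_len(n_frames)) {
    frames[seq_len(m), j] <- x[starts[j] + seq_len(m)] * w
  }
  X <- stats::mvfft(frames)
  n_bins <- nfft %/% 2L + 1L
  X <- X[seq_len(n_bins), , drop = FALSE]

  # Per-bin mean-square pressure: calibrated so a sine at a bin centre reports
  # its true mean square (amplitude a gives |X| = a * sum(w) / 2).
  scale <- (sum(w))^2
  ms <- Mod(X)^2 / scale
  two_sided <- rep(2, n_bins)
  two_sided[1L] <- 1
  if (nfft %% 2L == 0L) two_sided[n_bins] <- 1
  ms <- ms * two_sided
  level_db <- ifelse(ms > 0,
                     10 * log10(ms / P_REF^2) + rec$calibration_offset,
                     -Inf)

  structure(
    list(values = X,
         level_db = level_db,
         bin_freqs = (seq_len(n_bins) - 1L) * rec$sample_rate / nfft,
         frame_times = (starts + (m - 1) / 2) / rec$sample_rate,
         sample_rate = rec$sample_rate,
         fft_size = nfft, window_length = m, hop = hop,
         overlap = overlap, window = window,
         calibration_offset = rec$calibration_offset),
    class = "uroflow_stft"
  )
}

#' @export
print.uroflow_stft <- function(x, ...) {
  cat(sprintf("<uroflow_stft: %d bins x %d frames, fft %d, hop %d, %s window>\n",
              nrow(x$values), ncol(x$values), x$fft_size, x$hop, x$window))
  invisible(x)
}

#' Tidy a spectrogram into a long tibble
#'
#' @param x A `uroflow_stft`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `frequency`, `level_db`.
#' @export
tidy.uroflow_stft <- function(x, ...) {
  tibble(
    time = rep(x$frame_times, each = nrow(x$values)),
    frequency = rep(x$bin_freqs, times = ncol(x$values)),
    level_db = as.numeric(x$level_db)
  )
}

#' Write a spectrogram as self-describing delimited text
#'
#' Long-format CSV with one row per (frame, bin): `time_s`, `frequency_hz`,
#' `level_db`.
#'
#' @param x A `uroflow_stft`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(x, path) {
  stopifnot(inherits(x, "uroflow_stft"))
  df <- tidy(x)
  names(df) <- c("time_s", "frequency_hz", "level_db")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Least-squares overlap-add inverse of stft(); used to validate the frame /
# window conventions. Reconstructs the interior of the signal exactly where
# the squared-window overlap-add is positive.
istft_ols <- function(sp) {
  stopifnot(inherits(sp, "uroflow_stft"))
  m <- sp$window_length
  nfft <- sp$fft_size
  n_bins <- nrow(sp$values)
  n_frames <- ncol(sp$values)
  # rebuild two-sided spectra
  full <- matrix(0 + 0i, nrow = nfft, ncol = n_frames)
  full[seq_len(n_bins), ] <- sp$values
  if (nfft %% 2L == 0L) {
    full[seq(nfft, n_bins + 1L), ] <- Conj(sp$values[2:(n_bins - 1L), , drop = FALSE])
  } else {
    full[seq(nfft, n_bins + 1L), ] <- Conj(sp$values[2:n_bins, , drop = FALSE])
  }
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / nfft
  w <- if (sp$window == "hanning") hanning_window(m) else rep(1, m)
  n <- (n_frames - 1L) * sp$hop + m
  num <- numeric(n)
  den <- numeric(n)
  for (j in seq_len(n_frames)) {
    idx <- (j - 1L) * sp$hop + seq_len(m)
    num[idx] <- num[idx] + frames[seq_len(m), j] * w
    den[idx] <- den[idx] + w^2
  }
  out <- numeric(n)
  ok <- den > 1e-12
  out[ok] <- num[ok] / den[ok]
  list(samples = out, valid = ok)
}
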
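#' Frequency / critical-band-rate conversions
#'
#' Traunmüller's approximation of the Bark critical-band-rate scale,
#' invertible in closed form. 1 kHz maps to roughly 8.5 Bark.
#'
#' @param f Frequency in Hz.
#' @param z Critical-band rate in Bark.
#' @return `hz_to_bark()` returns Bark; `bark_to_hz()` returns Hz.
#' @export
hz_to_bark <- function(f) 26.81 * f / (1960 + f) - 0.53

#' @rdname hz_to_bark
#' @export
bark_to_hz <- function(z) 1960 * (z + 0.53) / (26.28 - z)

# Threshold in quiet (Terhardt), dB SPL, clamped below 20 Hz.
threshold_quiet_db <- function(f) {
  fk <- pmax(f, 20) / 1000
  3.64 * fk^-0.8 - 6.5 * exp(-0.6 * (fk - 3.3)^2) + 1e-3 * fk^4
}

# Critical-band channel index (width `step` Bark, channels covering 0-24 Bark)
# for each frequency; NA outside the Bark range.
bark_channel_index <- function(freqs, step = 0.5) {
  z <- hz_to_bark(freqs)
  idx <- floor(z / step) + 1L
  n_ch <- as.integer(round(24 / step))
  idx[z < 0 | z >= 24] <- NA_integer_
  attr(idx, "n_channels") <- n_ch
  attr(idx, "centers") <- (seq_len(n_ch) - 0.5) * step
  idx
}

# Channel intensity sums (linear, re I0) from one frame of bin levels in dB.
channel_levels_db <- function(level_db, channel_idx) {
  n_ch <- attr(channel_idx, "n_channels")
  ok <- !is.na(channel_idx)
  intens <- numeric(n_ch)
  if (any(ok)) {
    s <- rowsum(10^(level_db[ok] / 10), group = channel_idx[ok])
    intens[as.integer(rownames(s))] <- s[, 1L]
  }
  10 * log10(pmax(intens, 1e-30))
}

#' Bark-scale excitation pattern of one spectrogram frame
#'
#' Maps calibrated per-bin levels to critical-band channel levels, applies
#' level-dependent spreading across the Bark axis (27 dB/Bark lower skirt; an
#' upper skirt that flattens with level, Zwicker-style), and evaluates the
#' resulting excitation on a fixed fine Bark grid together with the
#' threshold-in-quiet excitation. Excitation is expressed as intensity
#' relative to \eqn{I_0 = 10^{-12}} W/m², i.e. \eqn{E/E_0 = 10^{L/10}}.
#'
#' @param level_db Numeric vector of one-sided bin levels (dB SPL) for a
#'   single frame, e.g. one column of `stft()$level_db`.
#' @param bin_freqs Bin frequencies in Hz, same length as `level_db`.
#' @param grid_step Bark grid resolution (default 0.1 Bark).
#' @param channel_step Critical-band channel width (default 0.5 Bark).
#' @return Object of class `bark_excitation`: list with `bark` (grid),
#'   `excitation` (E/E0, >= 0) and `threshold` (E_TQ/E0 per grid point).
#' @export
bark_excitation <- function(level_db, bin_freqs, grid_step = 0.1,
                            channel_step = 0.5) {
  if (length(level_db) != length(bin_freqs)) {
    abort_invalid("`level_db` and `bin_freqs` must have equal length")
  }
  idx <- bark_channel_index(bin_freqs, step = channel_step)
  l_ch <- channel_levels_db(level_db, idx)
  centers <- attr(idx, "centers")
  f_c <- bark_to_hz(centers)

  grid <- seq(0, 24, by = grid_step)
  E <- numeric(length(grid))
  active <- which(l_ch > -200)
  for (ch in active) {
    L <- l_ch[ch]
    dz <- grid - centers[ch]
    # lower skirt 27 dB/Bark; upper skirt flattens with band level
    s_up <- max(24 + 230 / f_c[ch] - 0.2 * L, 4)
    drop <- ifelse(dz < 0, -27 * dz, s_up * dz)
    E <- E + 10^((L - drop) / 10)
  }
  E[E < 1e-30] <- 0

  structure(
    list(bark = grid,
         excitation = E,
         threshold = 10^(threshold_quiet_db(bark_to_hz(pmin(grid, 23.9))) / 10)),
    class = "bark_excitation"
  )
}
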
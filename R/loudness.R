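#' Specific loudness from an excitation pattern
#'
#' Zwicker's power-law transformation of excitation into specific loudness
#' density (sone/Bark) per critical-band grid point:
#' \deqn{N' = 0.08 (E_{TQ}/E_0)^{0.23} [(0.5 + 0.5 E/E_{TQ})^{0.23} - 1]}
#' The raw expression is negative below the threshold in quiet; specific
#' loudness is nonnegative by definition, so it is clamped at zero there.
#'
#' @param exc A [bark_excitation()] (nonnegative excitation required).
#' @return Object of class `specific_loudness`: list with `bark` and `values`
#'   (sone/Bark, >= 0).
#' @export
specific_loudness <- function(exc) {
  stopifnot(inherits(exc, "bark_excitation"))
  if (any(exc$excitation < 0)) {
    abort_invalid("excitation must be nonnegative")
  }
  np <- 0.08 * exc$threshold^0.23 *
    ((0.5 + 0.5 * exc$excitation / exc$threshold)^0.23 - 1)
  structure(list(bark = exc$bark, values = pmax(np, 0)),
            class = "specific_loudness")
}

#' Total loudness of a specific-loudness pattern
#'
#' Integrates the specific loudness over the critical-band rate,
#' \eqn{N = \int_0^{24} N' \, dz}, by the trapezoid rule on the Bark grid.
#'
#' @param sl A [specific_loudness()].
#' @return Total loudness in sone (single nonnegative number).
#' @export
total_loudness <- function(sl) {
  stopifnot(inherits(sl, "specific_loudness"))
  max(pracma::trapz(sl$bark, sl$values), 0)
}

# Stationary loudness of one spectrogram frame (dB levels per bin).
frame_loudness <- function(level_db, bin_freqs) {
  total_loudness(specific_loudness(bark_excitation(level_db, bin_freqs)))
}

#' Frame-by-frame loudness of a recording
#'
#' Stationary Zwicker-style loudness per short-time frame, followed by
#' exponential smoothing (default time constant 50 ms) as a simple model of
#' temporal integration.
#'
#' @param rec A [sound_recording()].
#' @param fft_size,overlap STFT settings (defaults 4096 and 0.25).
#' @param smooth_s Exponential smoothing time constant in seconds; 0 disables.
#' @return Tibble with columns `time` (s) and `loudness` (sone).
#' @export
loudness_series <- function(rec, fft_size = 4096, overlap = 0.25,
                            smooth_s = 0.05) {
  sp <- stft(rec, fft_size = fft_size, overlap = overlap)
  n <- vapply(seq_len(ncol(sp$level_db)), function(j) {
    frame_loudness(sp$level_db[, j], sp$bin_freqs)
  }, numeric(1))
  if (smooth_s > 0 && length(n) > 1L) {
    dt <- sp$hop / sp$sample_rate
    alpha <- 1 - exp(-dt / smooth_s)
    for (j in 2:length(n)) n[j] <- n[j - 1] + alpha * (n[j] - n[j - 1])
  }
  tibble(time = sp$frame_times, loudness = n)
}
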
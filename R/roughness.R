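# One-time calibration scalar: chosen so the reference tone (1 kHz carrier at
# 60 dB SPL, 100% amplitude-modulated at 70 Hz) yields 1 asper, then frozen.
ROUGHNESS_CALIBRATION <- 0.15586695

#' Roughness configuration
#'
#' @param f_mod Modulation frequency in Hz whose band-level fluctuation drives
#'   roughness (default 70 Hz).
#' @param masking_cap Cap on the per-band masking depth in dB (default 50 dB,
#'   limiting background-noise influence).
#' @param calibration Dimensionless scale applied after the 0.3-prefactor
#'   Bark integral; the default makes the reference AM tone 1 asper.
#' @param block_s Analysis block length in seconds (default 0.2 s, about 14
#'   modulation periods at 70 Hz).
#' @param block_overlap Fractional overlap of consecutive blocks (default 0.5).
#' @return A list of class `roughness_config`.
#' @export
roughness_config <- function(f_mod = 70, masking_cap = 50,
                             calibration = ROUGHNESS_CALIBRATION,
                             block_s = 0.2, block_overlap = 0.5) {
  assert_scalar_number(f_mod, "f_mod", lower = 0, strict_lower = TRUE)
  assert_scalar_number(masking_cap, "masking_cap", lower = 0, strict_lower = TRUE)
  assert_scalar_number(calibration, "calibration", lower = 0, strict_lower = TRUE)
  assert_scalar_number(block_s, "block_s", lower = 0, strict_lower = TRUE)
  assert_scalar_number(block_overlap, "block_overlap", lower = 0, upper = 0.95)
  structure(list(f_mod = f_mod, masking_cap = masking_cap,
                 calibration = calibration, block_s = block_s,
                 block_overlap = block_overlap),
            class = "roughness_config")
}

#' Masking depth of a band-level envelope
#'
#' Peak-to-trough excursion (max minus min) of a critical-band level envelope
#' within an analysis block, clipped to `[0, cap]` dB.
#'
#' @param envelope Numeric vector of band levels in dB over one block.
#' @param cap Maximum depth in dB (default 50).
#' @return Masking depth in dB.
#' @export
masking_depth <- function(envelope, cap = 50) {
  if (length(envelope) == 0L) abort_invalid("empty envelope block")
  assert_scalar_number(cap, "cap", lower = 0, strict_lower = TRUE)
  env <- envelope[is.finite(envelope)]
  if (length(env) == 0L) return(0)
  min(max(max(env) - min(env), 0), cap)
}

# Critical-band level envelopes from a fine-hop secondary STFT: matrix of
# band levels (dB) sampled fast enough (default ~500 Hz) to resolve 70 Hz
# modulation. Returns list(times, levels [frames x channels], centers).
band_envelopes <- function(rec, window_length = 512, hop = 96,
                           channel_step = 0.5) {
  sp <- stft(rec, fft_size = window_length, window_length = window_length,
             overlap = 1 - hop / window_length)
  idx <- bark_channel_index(sp$bin_freqs, step = channel_step)
  n_ch <- attr(idx, "n_channels")
  ok <- which(!is.na(idx))
  intens <- matrix(0, nrow = ncol(sp$level_db), ncol = n_ch)
  lin <- 10^(sp$level_db[ok, , drop = FALSE] / 10)
  lin[!is.finite(lin)] <- 0
  grp <- idx[ok]
  agg <- rowsum(lin, group = grp)
  intens[, as.integer(rownames(agg))] <- t(agg)
  levels <- 10 * log10(pmax(intens, 1e-12))
  list(times = sp$frame_times, levels = levels,
       centers = attr(idx, "centers"), channel_step = channel_step,
       env_rate = rec$sample_rate / sp$hop)
}

#' Roughness from critical-band level envelopes
#'
#' Implements \eqn{R = c \cdot 0.3 \, f_{mod} \int_0^{24} \Delta L(z)\, dz}
#' with \eqn{f_{mod}} in kHz. The band-level envelopes are band-pass filtered
#' around the fixed modulation frequency, the masking depth \eqn{\Delta L(z)}
#' is the capped peak-to-trough excursion per analysis block and band, and the
#' Bark integral is taken over the channel grid. A fixed calibration scalar
#' `c` (fitted once on the reference AM tone, then frozen) expresses the
#' result in asper.
#'
#' @param levels Matrix of band levels in dB, frames x Bark channels.
#' @param times Frame times in seconds (strictly increasing, uniform).
#' @param cfg A [roughness_config()].
#' @param channel_step Bark width of each channel column (default 0.5).
#' @return Tibble with columns `time` (block centre, s) and
#'   `roughness` (asper).
#' @export
roughness_from_envelopes <- function(levels, times, cfg = roughness_config(),
                                     channel_step = 0.5) {
  stopifnot(is.matrix(levels))
  assert_times(times)
  if (nrow(levels) != length(times)) {
    abort_invalid("`levels` rows must match `times`")
  }
  span <- times[length(times)] - times[1L]
  if (span < 1 / cfg$f_mod) {
    abort_invalid("envelopes must span at least one modulation period")
  }
  fs_env <- 1 / stats::median(diff(times))

  filtered <- levels
  lo <- 0.5 * cfg$f_mod
  hi <- min(2 * cfg$f_mod, 0.45 * fs_env)
  if (hi > lo && fs_env > 2 * lo && nrow(levels) > 12L) {
    bf <- signal::butter(2, c(lo, hi) / (fs_env / 2), type = "pass")
    for (ch in seq_len(ncol(levels))) {
      col <- levels[, ch]
      if (max(col) - min(col) > 1e-9) {
        filtered[, ch] <- signal::filtfilt(bf, col)
      } else {
        filtered[, ch] <- 0
      }
    }
  } else {
    filtered <- sweep(levels, 2, colMeans(levels))
  }

  nb <- max(2L, as.integer(round(cfg$block_s * fs_env)))
  nb <- min(nb, nrow(filtered))
  step <- max(1L, as.integer(round(nb * (1 - cfg$block_overlap))))
  starts <- seq(1L, nrow(filtered) - nb + 1L, by = step)
  res <- vapply(starts, function(s) {
    seg <- filtered[s:(s + nb - 1L), , drop = FALSE]
    dl <- apply(seg, 2, masking_depth, cap = cfg$masking_cap)
    cfg$calibration * 0.3 * (cfg$f_mod / 1000) * sum(dl) * channel_step
  }, numeric(1))
  tibble(time = times[starts] + (nb - 1) / (2 * fs_env), roughness = res)
}

#' Roughness time series of a recording
#'
#' Computes fast critical-band level envelopes with a fine-hop short-time
#' analysis and applies [roughness_from_envelopes()].
#'
#' @param rec A [sound_recording()].
#' @param cfg A [roughness_config()].
#' @return Tibble with columns `time` (s) and `roughness` (asper).
#' @export
roughness <- function(rec, cfg = roughness_config()) {
  stopifnot(inherits(rec, "sound_recording"))
  env <- band_envelopes(rec)
  roughness_from_envelopes(env$levels, env$times, cfg = cfg,
                           channel_step = env$channel_step)
}
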
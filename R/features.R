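#' Loudness and roughness feature series of a recording
#'
#' The two psychoacoustic input features used by the flowrate models:
#' frame-by-frame total loudness (sone) and block-wise roughness (asper),
#' resampled by linear interpolation onto one common strictly increasing time
#' grid (the loudness frame grid restricted to the intersection of supports).
#'
#' @param rec A [sound_recording()].
#' @param fft_size,overlap Loudness STFT settings (defaults 4096 and 0.25).
#' @param cfg A [roughness_config()].
#' @return A `feature_series` tibble with columns `time` (s),
#'   `loudness` (sone) and `roughness` (asper).
#' @export
sound_features <- function(rec, fft_size = 4096, overlap = 0.25,
                           cfg = roughness_config()) {
  ldn <- loudness_series(rec, fft_size = fft_size, overlap = overlap)
  rgh <- roughness(rec, cfg = cfg)
  t_min <- max(min(ldn$time), min(rgh$time))
  t_max <- min(max(ldn$time), max(rgh$time))
  grid <- ldn$time[ldn$time >= t_min & ldn$time <= t_max]
  if (length(grid) < 1L) grid <- mean(c(t_min, t_max))
  new_feature_tbl(
    time = grid,
    loudness = pmax(interp_linear(ldn$time, ldn$loudness, grid), 0),
    roughness = pmax(interp_linear(rgh$time, rgh$roughness, grid), 0)
  )
}

#' Read / write feature series as delimited text
#'
#' Three-column CSV with header `time_s, loudness_sone, roughness_asper`.
#'
#' @param features A `feature_series` tibble (`time`, `loudness`,
#'   `roughness`).
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns a `feature_series` tibble.
#' @export
write_features <- function(features, path) {
  stopifnot(all(c("time", "loudness", "roughness") %in% names(features)))
  df <- data.frame(time_s = features$time,
                   loudness_sone = features$loudness,
                   roughness_asper = features$roughness)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "loudness_sone", "roughness_asper") %in% names(df))) {
    abort_invalid("feature file must have columns time_s, loudness_sone, roughness_asper")
  }
  new_feature_tbl(df$time_s, df$loudness_sone, df$roughness_asper)
}
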
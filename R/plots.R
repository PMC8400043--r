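#' Plot methods for pipeline result types
#'
#' `autoplot()` methods produce ggplot2 figures for the main result types:
#' spectrograms (time-frequency level map), flow curves, feature series
#' (loudness/roughness facets), and fitted models (training-loss curve).
#'
#' @param object The object to plot.
#' @param max_freq Upper frequency limit for spectrograms, Hz (default
#'   16 kHz, just above the top of the Bark range).
#' @param ... Unused.
#' @return A ggplot object.
#' @name sonouroflow-autoplot
NULL

#' @rdname sonouroflow-autoplot
#' @export
autoplot.uroflow_stft <- function(object, max_freq = 16000, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$frequency <= max_freq)
  floor_db <- max(df$level_db[is.finite(df$level_db)], -100) - 80
  df$level_db <- pmax(df$level_db, floor_db)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency,
                                   fill = .data$level_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB SPL") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)")
}

#' @rdname sonouroflow-autoplot
#' @export
autoplot.uroflow_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$flow)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "Time (s)", y = "Flowrate (mL/s)")
}

#' @rdname sonouroflow-autoplot
#' @export
autoplot.feature_series <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("loudness", "roughness"),
                            names_to = "feature")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Loudness (sone) / Roughness (asper)")
}

#' @rdname sonouroflow-autoplot
#' @export
autoplot.uroflow_regressor <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Mean squared error")
}

#' @rdname sonouroflow-autoplot
#' @export
autoplot.uroflow_classifier <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy")
}

#' Compare a predicted flowrate curve with the measurement
#'
#' @param pred,meas Flow tibbles (`time`, `flow`).
#' @return A ggplot object overlaying the two curves.
#' @export
plot_flow_comparison <- function(pred, meas) {
  df <- dplyr::bind_rows(
    mutate(as_tibble(pred)[c("time", "flow")], series = "predicted"),
    mutate(as_tibble(meas)[c("time", "flow")], series = "measured")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$flow,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Flowrate (mL/s)", colour = NULL)
}
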
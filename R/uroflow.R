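#' Flowrate curve from a urine weight trace
#'
#' The volume flowrate is the time derivative of the collected urine weight
#' divided by the urine density, \eqn{V(t) = \dot W(t) / \rho}. The weight
#' trace is smoothed with a short moving average before central-difference
#' differentiation (load-cell traces are noisy), and negative excursions are
#' clipped to zero.
#'
#' @param weights Data frame with columns `time` (s, strictly increasing) and
#'   `weight` (g); at least 3 samples.
#' @param density Urine density in g/mL (default 1.0).
#' @param smoothing Moving-average window in seconds applied to the weight
#'   before differentiation (default 0.5 s; 0 disables).
#' @return A `uroflow_curve` tibble with columns `time` (s) and
#'   `flow` (mL/s).
#' @export
flowrate_from_weight <- function(weights, density = 1.0, smoothing = 0.5) {
  stopifnot(all(c("time", "weight") %in% names(weights)))
  t <- weights$time
  w <- weights$weight
  if (length(t) < 3L) abort_invalid("weight trace needs at least 3 samples")
  assert_times(t)
  assert_scalar_number(density, "density", lower = 0, strict_lower = TRUE)
  dt <- stats::median(diff(t))
  if (smoothing > 0) w <- moving_average(w, round(smoothing / dt))
  n <- length(w)
  dw <- numeric(n)
  dw[2:(n - 1)] <- (w[3:n] - w[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  dw[1] <- (w[2] - w[1]) / (t[2] - t[1])
  dw[n] <- (w[n] - w[n - 1]) / (t[n] - t[n - 1])
  new_flow_tbl(t, pmax(dw / density, 0))
}

#' Voiding metrics of a flowrate curve
#'
#' Standard uroflowmetry summary: maximum flowrate (Qmax), voided volume
#' (trapezoid integral), voiding time (span between the first and last
#' crossing of `flow_threshold`), average flowrate, and the number of
#' interruptions. An interruption is a maximal sub-threshold gap of at least
#' `gap_s` seconds strictly inside the voiding span with substantive flow on
#' both sides (at least `max(2 * flow_threshold, 0.1 * q_max)`), so that
#' terminal or initial dribble is not miscounted as a stop-and-restart
#' event. Because reported average flowrates in
#' clinical tables are ambiguous about pauses, both definitions are returned:
#' `q_avg` = volume / voiding time, and `q_avg_flowing` = volume / time spent
#' above threshold.
#'
#' @param flow Data frame with columns `time` (s) and `flow` (mL/s).
#' @param flow_threshold Threshold defining the voiding span, mL/s
#'   (default 0.5).
#' @param gap_s Minimum sub-threshold gap duration counted as an interruption
#'   (default 1 s).
#' @return One-row tibble: `voided_volume` (mL), `voiding_time` (s), `q_max`,
#'   `q_avg`, `q_avg_flowing` (mL/s), `n_interruptions`.
#' @export
voiding_metrics <- function(flow, flow_threshold = 0.5, gap_s = 1) {
  stopifnot(all(c("time", "flow") %in% names(flow)))
  t <- flow$time
  v <- flow$flow
  if (length(t) < 1L) abort_invalid("empty flowrate curve")
  assert_times(t)
  if (any(v < 0) || any(!is.finite(v))) {
    abort_invalid("flowrate must be finite and nonnegative")
  }
  above <- which(v > flow_threshold)
  if (length(above) == 0L) {
    abort("flowrate never exceeds the threshold: no voiding event detected",
          class = "sonouroflow_no_void")
  }
  i0 <- above[1L]
  i1 <- above[length(above)]
  voiding_time <- t[i1] - t[i0]
  if (voiding_time <= 0) {
    abort("voiding span has zero duration", class = "sonouroflow_no_void")
  }
  vol <- pracma::trapz(t, v)

  # maximal sub-threshold runs strictly inside [i0, i1]; a run only counts as
  # an interruption when the stream resumes substantively on both sides
  inside <- seq(i0, i1)
  sub <- v[inside] <= flow_threshold
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  resume_level <- max(2 * flow_threshold, 0.1 * max(v))
  n_int <- 0L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    a <- inside[starts[k]]
    b <- inside[ends[k]]
    if (a <= i0 || b >= i1) next
    dur <- t[min(b + 1L, i1)] - t[max(a - 1L, i0)]
    if (dur >= gap_s &&
        max(v[i0:(a - 1L)]) >= resume_level &&
        max(v[(b + 1L):i1]) >= resume_level) {
      n_int <- n_int + 1L
    }
  }
  dt <- if (length(t) > 1L) stats::median(diff(t)) else 0
  flowing_time <- sum(v[inside] > flow_threshold) * dt
  tibble(
    voided_volume = vol,
    voiding_time = voiding_time,
    q_max = max(v),
    q_avg = vol / voiding_time,
    q_avg_flowing = if (flowing_time > 0) vol / flowing_time else NA_real_,
    n_interruptions = n_int
  )
}

# Count local maxima of the smoothed curve exceeding `frac` of the peak.
# The smoothing window scales with the voiding span so the count is invariant
# under uniform time stretching.
count_dominant_peaks <- function(t, v, frac = 0.5) {
  if (length(v) < 3L) return(as.integer(max(v) > 0))
  dt <- stats::median(diff(t))
  span <- t[length(t)] - t[1L]
  vs <- moving_average(v, round(span / 30 / dt))
  peak <- max(vs)
  if (peak <= 0) return(0L)
  dv <- diff(vs)
  # local maxima: derivative sign change + dominance threshold
  idx <- which(dv[-length(dv)] > 0 & dv[-1] <= 0) + 1L
  up <- vs[idx] > frac * peak
  # merge maxima not separated by a drop below frac * peak
  keep <- idx[up]
  if (length(keep) <= 1L) return(length(keep))
  count <- 1L
  last <- keep[1L]
  for (j in keep[-1L]) {
    if (min(vs[last:j]) < frac * peak) {
      count <- count + 1L
      last <- j
    }
  }
  count
}

#' Classify a flowrate curve into bladder-emptying patterns
#'
#' Deterministic rule-based labelling of the three clinically used curve
#' morphologies:
#' * `A` (healthy): bell-shaped — a single dominant peak, no interruptions,
#'   and Qmax above `a_threshold` (default 15 mL/s);
#' * `C` (obstruction/urinary impairment): Qmax below `c_threshold`
#'   (default 5 mL/s), or an interrupted curve with Qmax below
#'   `c_interrupted_threshold` (default 7.5 mL/s);
#' * `B` (staccato, LUTS / impaired detrusor contractility): everything else —
#'   fluctuating or low-flow curves that keep flowing.
#'
#' @param flow Data frame with columns `time` and `flow`.
#' @param a_threshold Minimum Qmax (mL/s) for the healthy bell label.
#' @param c_threshold Qmax (mL/s) below which the curve is labelled `C`.
#' @param c_interrupted_threshold Qmax bound for labelling interrupted curves
#'   `C`.
#' @param flow_threshold,gap_s Passed to [voiding_metrics()].
#' @return One-row tibble with `label` (factor A/B/C) and the metrics used as
#'   the decision basis.
#' @export
label_pattern <- function(flow, a_threshold = 15, c_threshold = 5,
                          c_interrupted_threshold = 7.5,
                          flow_threshold = 0.5, gap_s = 1) {
  m <- voiding_metrics(flow, flow_threshold = flow_threshold, gap_s = gap_s)
  n_peaks <- count_dominant_peaks(flow$time, flow$flow)
  bell <- (m$n_interruptions == 0L) && (n_peaks == 1L)
  label <- if (m$q_max < c_threshold ||
               (m$n_interruptions >= 1L && m$q_max < c_interrupted_threshold)) {
    "C"
  } else if (bell && m$q_max > a_threshold) {
    "A"
  } else {
    "B"
  }
  dplyr::bind_cols(
    tibble(label = factor(label, levels = c("A", "B", "C"))),
    m,
    tibble(n_peaks = n_peaks, bell_shaped = bell)
  )
}

#' Read / write two-column traces as delimited text
#'
#' Weight traces use header `time_s, weight_g`; flow curves use
#' `time_s, flow_ml_s`.
#'
#' @param x Data frame (`time` + `weight` or `time` + `flow`).
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_weight_trace <- function(x, path) {
  stopifnot(all(c("time", "weight") %in% names(x)))
  utils::write.csv(data.frame(time_s = x$time, weight_g = x$weight),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_trace
#' @export
read_weight_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "weight_g") %in% names(df))) {
    abort_invalid("weight trace file must have columns time_s, weight_g")
  }
  tibble(time = df$time_s, weight = df$weight_g)
}

#' @rdname write_weight_trace
#' @export
write_flow_curve <- function(x, path) {
  stopifnot(all(c("time", "flow") %in% names(x)))
  utils::write.csv(data.frame(time_s = x$time, flow_ml_s = x$flow),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_trace
#' @export
read_flow_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "flow_ml_s") %in% names(df))) {
    abort_invalid("flow curve file must have columns time_s, flow_ml_s")
  }
  new_flow_tbl(df$time_s, df$flow_ml_s)
}
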
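#' Generate a synthetic flowrate curve of a given archetype
#'
#' Seeded generator of the three clinically used flow-curve morphologies,
#' sampled at `rate` Hz (default 10 Hz, typical for uroflowmetry):
#' * `bell`: a gamma-shaped pulse (rapid initial rise, gradual decline)
#'   peaking at `q_max`; healthy curves require `q_max` > 15 mL/s;
#' * `staccato`: the bell modulated by `n_dips` sinusoidal dips of relative
#'   depth `dip_depth` that never reach zero flow; `q_max` < 10 mL/s;
#' * `interrupted`: `n_bursts` low-amplitude bursts separated by zero-flow
#'   gaps of at least 1 s; `q_max` < 5 mL/s.
#' The sampled maximum equals `q_max` exactly (the shape is rescaled).
#'
#' @param archetype One of `"bell"`, `"staccato"`, `"interrupted"`.
#' @param q_max Peak flowrate in mL/s; must honour the archetype's range.
#' @param voiding_time Nominal duration of the event in seconds.
#' @param n_dips Number of staccato dips (default 4).
#' @param dip_depth Relative depth of staccato dips in (0, 1) (default 0.6).
#' @param n_bursts Number of interrupted bursts (default 3).
#' @param rate Sampling rate in Hz (default 10).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return A `uroflow_curve` tibble (`time`, `flow`) with attribute
#'   `archetype`.
#' @export
gen_flow_curve <- function(archetype = c("bell", "staccato", "interrupted"),
                           q_max = NULL, voiding_time = NULL,
                           n_dips = 4, dip_depth = 0.6, n_bursts = 3,
                           rate = 10, seed = NULL) {
  archetype <- match.arg(archetype)
  if (!is.null(seed)) set.seed(seed)
  defaults <- list(bell = list(q_max = 22, voiding_time = 25),
                   staccato = list(q_max = 8, voiding_time = 45),
                   interrupted = list(q_max = 4, voiding_time = 60))
  if (is.null(q_max)) q_max <- defaults[[archetype]]$q_max
  if (is.null(voiding_time)) voiding_time <- defaults[[archetype]]$voiding_time
  assert_scalar_number(q_max, "q_max", lower = 0, strict_lower = TRUE)
  assert_scalar_number(voiding_time, "voiding_time", lower = 0,
                       strict_lower = TRUE)
  ok <- switch(archetype,
               bell = q_max > 15,
               staccato = q_max < 10,
               interrupted = q_max < 5)
  if (!ok) {
    abort_invalid(sprintf(
      "q_max = %g is inconsistent with the %s archetype (bell > 15, staccato < 10, interrupted < 5 mL/s)",
      q_max, archetype))
  }

  t <- seq(0, voiding_time, by = 1 / rate)
  gamma_pulse <- function(t, total, k = 4, peak_frac = 0.3) {
    tp <- peak_frac * total
    u <- pmax(t, 0) / tp
    u^k * exp(k * (1 - u))
  }

  v <- switch(archetype,
    bell = gamma_pulse(t, voiding_time),
    staccato = {
      # broad fluctuating envelope with a flow floor: the dips reduce but
      # never interrupt the stream (minimum stays near 18% of the peak)
      env <- sin(pi * t / voiding_time)^0.7
      phase <- runif(1, 0, pi)
      dips <- 1 - dip_depth * sin(pi * n_dips * t / voiding_time + phase)^2
      ramp <- min(2, voiding_time / 10)
      taper <- pmin(1, t / ramp, (voiding_time - t) / ramp)
      (0.18 + 0.82 * env * dips) * taper
    },
    interrupted = {
      n_bursts <- max(1L, as.integer(n_bursts))
      gap <- runif(n_bursts - 1L, 1.5, 3.5)
      burst_len <- (voiding_time - sum(gap)) / n_bursts
      if (burst_len < 1) {
        abort_invalid("voiding_time too short for the requested bursts")
      }
      amp <- runif(n_bursts, 0.55, 1)
      amp[sample.int(n_bursts, 1L)] <- 1
      starts <- cumsum(c(0, rep(burst_len, n_bursts - 1L) + gap))
      v <- numeric(length(t))
      for (b in seq_len(n_bursts)) {
        inb <- t >= starts[b] & t <= starts[b] + burst_len
        v[inb] <- v[inb] + amp[b] * sin(pi * (t[inb] - starts[b]) / burst_len)^2
      }
      v
    }
  )
  v <- v / max(v) * q_max
  out <- new_flow_tbl(t, v)
  attr(out, "archetype") <- archetype
  out
}

#' Generate a load-cell weight trace from a flowrate curve
#'
#' Inverts the flowrate relation \eqn{V = \dot W/\rho}: the weight is the
#' cumulative trapezoid integral of \eqn{\rho V(t)} (nondecreasing), plus
#' optional i.i.d. Gaussian measurement noise.
#'
#' @param flow Flow tibble (`time`, `flow`).
#' @param density Urine density in g/mL (default 1.0).
#' @param noise_g Standard deviation of additive weight noise in grams
#'   (default 0).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return Tibble with columns `time` (s) and `weight` (g).
#' @export
gen_weight_trace <- function(flow, density = 1.0, noise_g = 0, seed = NULL) {
  stopifnot(all(c("time", "flow") %in% names(flow)))
  assert_scalar_number(density, "density", lower = 0, strict_lower = TRUE)
  assert_scalar_number(noise_g, "noise_g", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  w <- density * pracma::cumtrapz(flow$time, flow$flow)[, 1L]
  if (noise_g > 0) w <- w + rnorm(length(w), 0, noise_g)
  tibble(time = flow$time, weight = w)
}

#' Forward model: sound features from a flowrate curve
#'
#' Emulates the empirical co-variation of voiding-sound loudness and
#' roughness with the flowrate: loudness follows a compressive power law of
#' the flowrate, roughness is proportional to it, and both carry
#' multiplicative Gaussian observation noise. This is a test harness for the
#' learning pipeline, not an acoustic simulation.
#'
#' @param flow Flow tibble (`time`, `flow`).
#' @param loudness_gain Sone per (mL/s)^`gamma` (default 2).
#' @param roughness_gain Asper per (mL/s) (default 0.05).
#' @param gamma Loudness compression exponent (default 0.6).
#' @param noise Fractional standard deviation of the multiplicative
#'   observation noise (default 0.05).
#' @param lag Time shift of the features relative to the flow, s (default 0).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return A `feature_series` tibble (`time`, `loudness`, `roughness`).
#' @export
gen_sound_features <- function(flow, loudness_gain = 2, roughness_gain = 0.05,
                               gamma = 0.6, noise = 0.05, lag = 0,
                               seed = NULL) {
  stopifnot(all(c("time", "flow") %in% names(flow)))
  assert_scalar_number(loudness_gain, "loudness_gain", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(roughness_gain, "roughness_gain", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(noise, "noise", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(flow)
  eps_l <- if (noise > 0) rnorm(n, 0, noise) else numeric(n)
  eps_r <- if (noise > 0) rnorm(n, 0, noise) else numeric(n)
  new_feature_tbl(
    time = flow$time + lag,
    loudness = pmax(loudness_gain * flow$flow^gamma * (1 + eps_l), 0),
    roughness = pmax(roughness_gain * flow$flow * (1 + eps_r), 0)
  )
}

#' Generate an amplitude-modulated calibration tone
#'
#' \eqn{p(t) = p_0 (1 + d \sin 2\pi f_m t) \sin 2\pi f_c t}, with \eqn{p_0}
#' chosen so the total RMS sound pressure matches the requested level in
#' dB SPL re 20 µPa. The defaults generate the roughness reference: a 1 kHz
#' carrier at 60 dB, 100% amplitude-modulated at 70 Hz.
#'
#' @param carrier Carrier frequency in Hz (default 1000; must be below the
#'   Nyquist frequency).
#' @param level Sound pressure level in dB SPL (default 60).
#' @param mod_freq Modulation frequency in Hz (default 70).
#' @param mod_depth Modulation depth in `[0, 1]` (default 1).
#' @param duration Duration in seconds (default 2).
#' @param rate Sample rate in Hz (default 48000).
#' @return A [sound_recording()] with samples in pascals.
#' @export
gen_am_tone <- function(carrier = 1000, level = 60, mod_freq = 70,
                        mod_depth = 1, duration = 2, rate = 48000) {
  assert_scalar_number(carrier, "carrier", lower = 0, strict_lower = TRUE)
  assert_scalar_number(rate, "rate", lower = 0, strict_lower = TRUE)
  if (carrier >= rate / 2) {
    abort_invalid("carrier must be below the Nyquist frequency")
  }
  assert_scalar_number(mod_depth, "mod_depth", lower = 0, upper = 1)
  t <- seq(0, duration, by = 1 / rate)
  p_rms <- P_REF * 10^(level / 20)
  # RMS of (1 + d sin) * sin is p0 * sqrt((1 + d^2/2) / 2)
  p0 <- p_rms / sqrt((1 + mod_depth^2 / 2) / 2)
  p <- p0 * (1 + mod_depth * sin(2 * pi * mod_freq * t)) *
    sin(2 * pi * carrier * t)
  sound_recording(p, rate)
}

#' Generate a labelled synthetic cohort of voiding events
#'
#' Draws `n_per_class` events per pattern class with archetype parameters
#' sampled from clinically plausible ranges that honour the labelling
#' thresholds (bell Qmax 16–35 mL/s over 12–40 s; staccato Qmax 5.5–9.5 mL/s
#' over 30–70 s; interrupted Qmax 2.5–4.8 mL/s over 40–90 s), together with a
#' matched weight trace and a paired sound-feature series from the forward
#' model. Fully reproducible from `seed`.
#'
#' @param n_per_class Events per class (default 10).
#' @param seed Integer seed (default 0).
#' @param noise Fractional feature observation noise (default 0.05).
#' @param weight_noise_g Weight-trace noise in grams (default 0.5).
#' @return Tibble with columns `patient`, `label` (factor A/B/C),
#'   `archetype`, and list-columns `flow`, `weight`, `features`.
#' @export
gen_cohort <- function(n_per_class = 10, seed = 0, noise = 0.05,
                       weight_noise_g = 0.5) {
  assert_scalar_number(n_per_class, "n_per_class", lower = 1)
  set.seed(seed)
  classes <- tibble(
    archetype = c("bell", "staccato", "interrupted"),
    label = c("A", "B", "C")
  )
  rows <- purrr::map_dfr(seq_len(nrow(classes)), function(ci) {
    purrr::map_dfr(seq_len(as.integer(n_per_class)), function(k) {
      arch <- classes$archetype[ci]
      spec <- switch(arch,
        bell = list(q_max = runif(1, 16, 35), vt = runif(1, 12, 40)),
        staccato = list(q_max = runif(1, 5.5, 9.5), vt = runif(1, 30, 70)),
        interrupted = list(q_max = runif(1, 2.5, 4.8), vt = runif(1, 40, 90))
      )
      fc <- gen_flow_curve(arch, q_max = spec$q_max, voiding_time = spec$vt,
                           n_dips = sample(3:6, 1), dip_depth = runif(1, 0.5, 0.8),
                           n_bursts = sample(3:5, 1), seed = NULL)
      tibble(
        patient = sprintf("%s%02d", classes$label[ci], k),
        label = classes$label[ci],
        archetype = arch,
        flow = list(fc),
        weight = list(gen_weight_trace(fc, noise_g = weight_noise_g,
                                       seed = NULL)),
        features = list(gen_sound_features(fc, noise = noise, seed = NULL))
      )
    })
  })
  rows$label <- factor(rows$label, levels = c("A", "B", "C"))
  rows
}
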
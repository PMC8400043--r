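# Small internal helpers shared across modules.

# Sound pressure reference, 20 micropascal.
P_REF <- 2e-5

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s]",
                  name, if (strict_lower) "(" else "[", lower, upper),
          class = "sonouroflow_invalid_argument")
  }
  invisible(x)
}

abort_invalid <- function(msg) {
  abort(msg, class = "sonouroflow_invalid_argument")
}

# Strictly increasing numeric time vector check.
assert_times <- function(times, name = "time") {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times) ||
      (length(times) > 1L && any(diff(times) <= 0))) {
    abort_invalid(sprintf("`%s` must be strictly increasing and finite", name))
  }
  invisible(times)
}

# Linear interpolation clamped to the source support (rule = 2 at both ends).
interp_linear <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 2)$y
}

new_flow_tbl <- function(time, flow) {
  out <- tibble(time = as.numeric(time), flow = as.numeric(flow))
  class(out) <- c("uroflow_curve", class(out))
  out
}

new_feature_tbl <- function(time, loudness, roughness) {
  out <- tibble(time = as.numeric(time), loudness = as.numeric(loudness),
                roughness = as.numeric(roughness))
  class(out) <- c("feature_series", class(out))
  out
}

# Moving-average smoother with edge shrinkage (window in samples, forced odd).
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < 3L) return(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
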
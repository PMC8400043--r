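test_that("excitation pattern: silence, tone placement, intensity additivity", {
  fs <- 48000
  silent <- stft(sound_recording(rep(0, fs / 2), fs))
  exc0 <- bark_excitation(silent$level_db[, 1], silent$bin_freqs)
  expect_true(all(exc0$excitation == 0))

  # 1 kHz tone peaks in the critical band containing ~8.5 Bark
  tone <- gen_am_tone(carrier = 1000, level = 60, mod_depth = 0, duration = 0.3)
  sp <- stft(tone)
  exc <- bark_excitation(sp$level_db[, 2], sp$bin_freqs)
  z_peak <- exc$bark[which.max(exc$excitation)]
  expect_lt(abs(z_peak - hz_to_bark(1000)), 0.5)

  # two tones in disjoint bands: excitation adds bandwise (intensity additivity)
  t <- seq(0, 0.3, by = 1 / fs)
  p1 <- 0.02 * sin(2 * pi * 1000 * t)
  p2 <- 0.02 * sin(2 * pi * 8000 * t)
  e1 <- bark_excitation(stft(sound_recording(p1, fs))$level_db[, 2],
                        sp$bin_freqs)$excitation
  e2 <- bark_excitation(stft(sound_recording(p2, fs))$level_db[, 2],
                        sp$bin_freqs)$excitation
  e12 <- bark_excitation(stft(sound_recording(p1 + p2, fs))$level_db[, 2],
                         sp$bin_freqs)$excitation
  big <- e1 + e2 > 0.01 * max(e1 + e2)
  expect_equal(e12[big], (e1 + e2)[big], tolerance = 0.05)
})

test_that("specific loudness follows the excitation power law", {
  z <- seq(0, 24, by = 0.1)
  etq <- rep(10, length(z))

  # E = E_TQ: bracket term (1)^0.23 - 1 vanishes
  sl <- specific_loudness(manual_excitation(z, etq, etq))
  expect_true(all(sl$values == 0))

  # E = 0: raw bracket negative, clamped at zero
  sl0 <- specific_loudness(manual_excitation(z, 0 * etq, etq))
  expect_true(all(sl0$values == 0))

  # E = 3 E_TQ with E_TQ/E0 = 10: direct evaluation of the closed form
  sl3 <- specific_loudness(manual_excitation(z, 3 * etq, etq))
  expect_equal(unique(sl3$values), 0.0234812684365, tolerance = 1e-9)

  expect_error(specific_loudness(manual_excitation(z, -etq, etq)),
               class = "sonouroflow_invalid_argument")

  # asymptotic power law: N'(100 E)/N'(E) -> 100^0.23 for E >> E_TQ
  e_big <- 1e6 * etq
  r <- specific_loudness(manual_excitation(z, 100 * e_big, etq))$values /
    specific_loudness(manual_excitation(z, e_big, etq))$values
  expect_equal(unique(r), 100^0.23, tolerance = 0.05)
})

test_that("total loudness integrates specific loudness over the Bark axis", {
  z <- seq(0, 24, by = 0.1)
  zero <- structure(list(bark = z, values = rep(0, length(z))),
                    class = "specific_loudness")
  expect_equal(total_loudness(zero), 0)

  one <- structure(list(bark = z, values = rep(1, length(z))),
                   class = "specific_loudness")
  expect_equal(total_loudness(one), 24)

  # piecewise-linear pattern against an independent fine-grid quadrature
  vals <- pmax(0, 1 - abs(z - 12) / 6)
  pl <- structure(list(bark = z, values = vals), class = "specific_loudness")
  zf <- seq(0, 24, by = 1e-4)
  oracle <- sum(diff(zf) * (head(pmax(0, 1 - abs(zf - 12) / 6), -1) +
                              tail(pmax(0, 1 - abs(zf - 12) / 6), -1)) / 2)
  expect_equal(total_loudness(pl), oracle, tolerance = 1e-9)
})

test_that("loudness never decreases when the signal is amplified", {
  set.seed(4)
  x <- rnorm(24000)
  l1 <- loudness_series(sound_recording(0.005 * x, 48000))
  l2 <- loudness_series(sound_recording(0.05 * x, 48000))
  expect_true(all(l2$loudness >= l1$loudness))

  # a ramped tone gives a monotone nondecreasing loudness series
  t <- seq(0, 1, by = 1 / 48000)
  ramp <- 0.002 + 0.05 * t
  rec <- sound_recording(ramp * sin(2 * pi * 1000 * t), 48000)
  ls <- loudness_series(rec)
  expect_true(all(diff(ls$loudness) > -1e-9))
})

test_that("masking depth is the capped peak-to-trough band fluctuation", {
  expect_equal(masking_depth(rep(60, 100)), 0)
  expect_equal(masking_depth(seq(20, 100, length.out = 50), cap = 50), 50)
  env <- 60 + 5 * sin(seq(0, 4 * pi, length.out = 200))
  expect_equal(masking_depth(env), 10, tolerance = 1e-3)
  expect_error(masking_depth(numeric(0)),
               class = "sonouroflow_invalid_argument")
})

test_that("roughness is linear in masking depth and zero without modulation", {
  # synthetic band envelopes: one channel modulated at 70 Hz
  fs_env <- 500
  tt <- seq(0, 1, by = 1 / fs_env)
  lev <- matrix(60, nrow = length(tt), ncol = 48)
  lev[, 18] <- 60 + 5 * sin(2 * pi * 70 * tt)
  cfg <- roughness_config(calibration = 1)
  r1 <- roughness_from_envelopes(lev, tt, cfg)
  lev2 <- lev
  lev2[, 18] <- 60 + 10 * sin(2 * pi * 70 * tt)
  r2 <- roughness_from_envelopes(lev2, tt, cfg)
  expect_gt(median(r1$roughness), 0)
  expect_equal(median(r2$roughness) / median(r1$roughness), 2,
               tolerance = 1e-6)

  # constant envelopes: zero roughness
  r0 <- roughness_from_envelopes(matrix(60, length(tt), 48), tt, cfg)
  expect_equal(max(r0$roughness), 0)

  # block shorter than one modulation period
  expect_error(
    roughness_from_envelopes(lev[1:5, , drop = FALSE], tt[1:5], cfg),
    class = "sonouroflow_invalid_argument")

  # an unmodulated stationary tone is essentially smooth
  pure <- gen_am_tone(mod_depth = 0, duration = 1)
  expect_lt(median(roughness(pure)$roughness), 0.05)
})

test_that("the reference AM tone yields one asper", {
  tone <- gen_am_tone(carrier = 1000, level = 60, mod_freq = 70,
                      mod_depth = 1, duration = 2, rate = 48000)
  r <- median(roughness(tone)$roughness)
  expect_equal(r, 1, tolerance = 0.1)
})

test_that("feature series share one grid and track the sound", {
  silent <- sound_recording(rep(0, 48000), 48000)
  fs <- sound_features(silent)
  expect_true(all(fs$loudness == 0) && all(fs$roughness == 0))
  expect_true(all(diff(fs$time) > 0))

  tone <- gen_am_tone(duration = 1.2)
  ft <- sound_features(tone)
  expect_identical(nrow(ft), length(ft$roughness))
  expect_true(all(ft$loudness > 0))
  expect_equal(median(ft$roughness), 1, tolerance = 0.15)
})

test_that("synthetic voiding features peak with the flowrate", {
  fc <- gen_flow_curve("bell", q_max = 20, voiding_time = 30, seed = 5)
  fs <- gen_sound_features(fc, noise = 0)
  expect_lt(abs(fs$time[which.max(fs$loudness)] -
                  fc$time[which.max(fc$flow)]), 0.5)
  expect_lt(abs(fs$time[which.max(fs$roughness)] -
                  fc$time[which.max(fc$flow)]), 0.5)
})
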
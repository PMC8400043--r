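test_that("feature/flow alignment interpolates onto a common uniform grid", {
  t <- seq(0, 10, by = 0.1)
  fs <- tibble::tibble(time = t, loudness = t, roughness = 2 * t)
  fc <- tibble::tibble(time = t, flow = 3 * t)
  al <- align_features_to_flow(fs, fc)
  expect_equal(al$time, t)
  expect_equal(al$loudness, fs$loudness)
  expect_equal(al$flow, fc$flow)

  # feature grid at twice the flow rate: output uses the coarser grid
  fs2 <- tibble::tibble(time = seq(0, 10, by = 0.05),
                        loudness = seq(0, 10, by = 0.05),
                        roughness = 1)
  al2 <- align_features_to_flow(fs2, fc)
  expect_equal(median(diff(al2$time)), 0.1)
  expect_equal(al2$loudness, al2$time, tolerance = 1e-9)

  # aligned synthetic pair with no lag has its cross-correlation peak at 0
  fc3 <- gen_flow_curve("bell", seed = 31)
  ft3 <- gen_sound_features(fc3, noise = 0)
  al3 <- align_features_to_flow(ft3, fc3)
  cc <- ccf(al3$roughness, al3$flow, lag.max = 20, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)

  fs_off <- tibble::tibble(time = t + 100, loudness = 1, roughness = 1)
  expect_error(align_features_to_flow(fs_off, fc),
               class = "sonouroflow_invalid_argument")
})

test_that("normalization maps to the unit square at fixed length", {
  fc <- gen_flow_curve("staccato", seed = 32)
  ns <- normalize_resample(fc)
  expect_identical(nrow(ns), 246L)
  expect_true(all(ns$flow >= 0 & ns$flow <= 1))
  expect_equal(range(ns$time), c(0, 1))
  expect_equal(max(ns$flow), 1)

  const <- tibble::tibble(time = 0:10, flow = rep(4, 11))
  expect_true(all(normalize_resample(const)$flow == 1))

  # invertible within interpolation error
  back <- denormalize_sequence(ns)
  err <- max(abs(interp_linear(back$time, back$flow, fc$time) - fc$flow))
  expect_lt(err / max(fc$flow), 0.01)

  # idempotent
  ns2 <- normalize_resample(ns)
  expect_equal(ns2$flow, ns$flow, tolerance = 1e-12)

  expect_error(normalize_resample(tibble::tibble(time = 0:5, flow = rep(0, 6))),
               class = "sonouroflow_invalid_argument")
})

test_that("augmentation respects the amplitude bound and the seed", {
  fc <- gen_flow_curve("bell", q_max = 20, voiding_time = 25, seed = 33)
  copies <- augment_flow(fc, n_copies = 100, seed = 7)
  expect_identical(length(unique(copies$copy)), 100L)
  worst <- copies |>
    dplyr::group_by(copy) |>
    dplyr::summarise(d = max(abs(flow - fc$flow))) |>
    dplyr::pull(d)
  expect_true(all(worst < 0.05 * max(fc$flow)))
  expect_true(all(copies$flow >= 0))

  # degenerate zero amplitude leaves the curve unchanged
  same <- augment_flow(fc, n_copies = 2, amplitude_fraction = 0, seed = 1)
  expect_equal(same$flow, rep(fc$flow, 2))

  # determinism
  again <- augment_flow(fc, n_copies = 100, seed = 7)
  expect_identical(copies, again)
})

test_that("augmentation never changes the pattern label", {
  for (arch in c("bell", "staccato", "interrupted")) {
    fc <- gen_flow_curve(arch, seed = 34)
    base <- as.character(label_pattern(fc)$label)
    copies <- augment_flow(fc, n_copies = 25, seed = 34)
    labs <- vapply(split(copies, copies$copy), function(cp) {
      as.character(label_pattern(cp[c("time", "flow")])$label)
    }, character(1))
    expect_true(all(labs == base), info = arch)
  }
})

test_that("training sets split patient-wise without leakage", {
  co <- small_cohort()
  ts <- build_training_set(co, task = "classification", split_fraction = 0.75,
                           n_copies = 5, seed = 3)
  tr_pat <- unique(vapply(ts$train, function(e) e$patient, character(1)))
  va_pat <- unique(vapply(ts$validation, function(e) e$patient, character(1)))
  expect_length(intersect(tr_pat, va_pat), 0)
  expect_identical(length(ts$train), length(tr_pat) * 5L)
  expect_true(all(vapply(ts$train, function(e) length(e$x), integer(1)) == 246L))

  # same seed reproduces the same split and examples
  ts2 <- build_training_set(co, task = "classification",
                            split_fraction = 0.75, n_copies = 5, seed = 3)
  expect_identical(ts$train_patients, ts2$train_patients)
  expect_equal(ts$train[[1]]$x, ts2$train[[1]]$x)

  # regression: standardization statistics come from train patients only
  tr <- build_training_set(co, task = "regression", split_fraction = 0.75,
                           seed = 3)
  xtr <- do.call(rbind, lapply(tr$train, function(e) e$x))
  expect_equal(colMeans(xtr), c(loudness = 0, roughness = 0),
               tolerance = 1e-10)
  expect_equal(apply(xtr, 2, sd), c(loudness = 1, roughness = 1),
               tolerance = 1e-10)
  xva <- do.call(rbind, lapply(tr$validation, function(e) e$x))
  expect_gt(max(abs(colMeans(xva))), 1e-6)
  expect_equal(max(vapply(tr$train, function(e) max(e$y), numeric(1))), 1,
               tolerance = 1e-12)
})
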
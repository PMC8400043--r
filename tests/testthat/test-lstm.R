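test_that("the LSTM cell step matches hand-computed values", {
  H <- 3; D <- 2
  zeros <- list(
    W_f = matrix(0, H, H + D), b_f = numeric(H),
    W_i = matrix(0, H, H + D), b_i = numeric(H),
    W_c = matrix(0, H, H + D), b_c = numeric(H),
    W_o = matrix(0, H, H + D), b_o = numeric(H))
  s1 <- lstm_cell_step(c(1, -1), list(h = numeric(H), c = numeric(H)), zeros)
  # sigma(0) = 0.5, tanh(0) = 0: candidate 0, so c and h stay 0
  expect_equal(s1$c, numeric(H))
  expect_equal(s1$h, numeric(H))

  s2 <- lstm_cell_step(c(1, -1), list(h = numeric(H), c = rep(1, H)), zeros)
  expect_equal(s2$c, rep(0.5, H))
  expect_equal(s2$h, rep(0.5 * tanh(0.5), H))

  bad <- zeros
  bad$W_f <- matrix(0, H, H + D + 1)
  expect_error(lstm_cell_step(c(1, -1), list(h = numeric(H), c = numeric(H)), bad),
               class = "sonouroflow_invalid_argument")
})

test_that("compiled forward pass agrees with the step-by-step reference", {
  set.seed(101)
  worst <- 0
  for (rep in 1:100) {
    H <- sample(1:6, 1)
    D <- sample(1:3, 1)
    p <- random_packed_params(D, H)
    gp <- sonouroflow:::unpack_gate_params(p)
    x <- matrix(rnorm(10 * D), 10, D)
    fw <- sonouroflow:::cpp_lstm_forward(p$Wg, p$b, x)
    st <- list(h = numeric(H), c = numeric(H))
    for (t in 1:10) st <- lstm_cell_step(x[t, ], st, gp)
    worst <- max(worst, abs(st$h - fw$h[10, ]), abs(st$c - fw$c[10, ]))
    expect_true(all(abs(fw$h) < 1))  # gate-bounded hidden state
  }
  expect_lt(worst, 1e-6)
})

test_that("zero-weight heads give uninformative outputs", {
  clf <- zero_classifier()
  res <- classify_pattern(clf, rep(0.5, 246))
  expect_equal(unlist(res[c("A", "B", "C")], use.names = FALSE), rep(1 / 3, 3))
  expect_equal(sum(unlist(res[c("A", "B", "C")])), 1, tolerance = 1e-9)
  expect_error(classify_pattern(clf, rep(0.5, 100)),
               class = "sonouroflow_invalid_argument")
})

test_that("softmax probabilities always sum to one", {
  fit <- small_regressor()
  co <- small_cohort()
  ts <- build_training_set(co, task = "classification", n_copies = 3,
                           split_fraction = 0.75, seed = 5)
  clf <- train_pattern_classifier(ts, hidden_size = 8, epochs = 3, seed = 5)
  for (e in ts$validation[1:5]) {
    res <- classify_pattern(clf, e$x)
    p <- unlist(res[c("A", "B", "C")])
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("training is deterministic given the seed", {
  ts <- small_regressor()$ts
  m1 <- train_flow_regressor(ts, epochs = 5, seed = 9)
  m2 <- train_flow_regressor(ts, epochs = 5, seed = 9)
  expect_identical(m1$params$Wg, m2$params$Wg)
  expect_identical(m1$loss, m2$loss)
  m3 <- train_flow_regressor(ts, epochs = 5, seed = 10)
  expect_false(identical(m1$params$Wg, m3$params$Wg))
})

test_that("training loss decreases over epochs", {
  fit <- small_regressor()
  loss <- fit$model$loss
  expect_lt(loss[length(loss)], loss[1])
  expect_lt(mean(tail(loss, 5)), mean(head(loss, 5)))
  # allow only modest upticks in the epoch-averaged trend
  upticks <- diff(loss) / head(loss, -1)
  expect_true(all(upticks < 0.10))
})

test_that("a noiseless linear feature-flow mapping is recovered", {
  co <- gen_cohort(17, seed = 7, noise = 0)
  co$features <- lapply(co$flow, function(fc) {
    gen_sound_features(fc, gamma = 1, noise = 0)
  })
  ts <- build_training_set(co, task = "regression", split_fraction = 0.8,
                           seed = 7)
  m <- train_flow_regressor(ts, epochs = 150, seed = 7)
  ev <- evaluate_flow_predictions(m, ts)
  expect_lt(mean(ev$error_rate), 2)
})

test_that("the regressor is causal: reversed input differs from reversed output", {
  fit <- small_regressor()
  e <- fit$ts$validation[[1]]
  sc <- fit$ts$scaling
  feats <- tibble::tibble(
    time = e$time,
    loudness = e$x[, 1] * sc$x_sd[["loudness"]] + sc$x_mean[["loudness"]],
    roughness = e$x[, 2] * sc$x_sd[["roughness"]] + sc$x_mean[["roughness"]])
  fwd <- predict_flowrate(fit$model, feats)
  rev_feats <- dplyr::mutate(feats,
                             loudness = rev(loudness),
                             roughness = rev(roughness))
  bwd <- predict_flowrate(fit$model, rev_feats)
  expect_gt(max(abs(rev(bwd$flow) - fwd$flow)), 1e-6)
})

test_that("class probabilities are permutation-equivariant at the head", {
  co <- small_cohort()
  ts <- build_training_set(co, task = "classification", n_copies = 3,
                           split_fraction = 0.75, seed = 6)
  clf <- train_pattern_classifier(ts, hidden_size = 8, epochs = 3, seed = 6)
  x <- ts$validation[[1]]$x
  p0 <- unlist(classify_pattern(clf, x)[c("A", "B", "C")])
  perm <- c(3, 1, 2)
  clf2 <- clf
  clf2$params$Wy <- clf$params$Wy[perm, , drop = FALSE]
  clf2$params$by <- clf$params$by[perm]
  p1 <- unlist(classify_pattern(clf2, x)[c("A", "B", "C")])
  expect_equal(as.numeric(p1), as.numeric(p0[perm]), tolerance = 1e-12)
})

test_that("label-permuted training collapses to chance accuracy", {
  co <- gen_cohort(4, seed = 41)
  # break the label-curve association completely
  set.seed(41)
  co$label <- sample(co$label)
  ts <- build_training_set(co, task = "classification", n_copies = 10,
                           split_fraction = 0.75, seed = 41)
  clf <- train_pattern_classifier(ts, hidden_size = 10, epochs = 10, seed = 41)
  ev <- evaluate_classifications(clf, ts)
  expect_lte(mean(ev$predicted == ev$label), 0.5)
})

test_that("error-rate arithmetic matches direct computation", {
  t <- seq(0, 10, by = 0.1)
  meas <- tibble::tibble(time = t, flow = 10 * exp(-(t - 5)^2 / 4))
  expect_equal(flow_error_rate(meas, meas), 0)
  pred <- dplyr::mutate(meas, flow = flow + 0.05 * max(meas$flow))
  expect_equal(flow_error_rate(pred, meas), 5, tolerance = 1e-9)

  # zero prediction against a rectangular pulse over half the grid
  n <- length(t)
  rect <- tibble::tibble(time = t, flow = ifelse(seq_len(n) <= n / 2, 10, 0))
  zero <- tibble::tibble(time = t, flow = rep(0, n))
  expect_equal(flow_error_rate(zero, rect), 100 * mean(rect$flow) / 10,
               tolerance = 1e-9)
  expect_equal(flow_error_rate(zero, rect), 50, tolerance = 1)

  expect_error(flow_error_rate(zero, zero),
               class = "sonouroflow_invalid_argument")
})

test_that("models round-trip through the JSON serialization", {
  fit <- small_regressor()
  p <- tempfile(fileext = ".json")
  write_model(fit$model, p)
  back <- read_model(p)
  e <- fit$ts$validation[[1]]
  sc <- fit$ts$scaling
  feats <- tibble::tibble(
    time = e$time,
    loudness = e$x[, 1] * sc$x_sd[["loudness"]] + sc$x_mean[["loudness"]],
    roughness = e$x[, 2] * sc$x_sd[["roughness"]] + sc$x_mean[["roughness"]])
  expect_equal(predict_flowrate(back, feats)$flow,
               predict_flowrate(fit$model, feats)$flow, tolerance = 1e-12)
  unlink(p)
})

test_that("tidy and glance summarise fitted models", {
  fit <- small_regressor()
  td <- tidy(fit$model)
  expect_true(all(c("parameter", "row", "col", "value") %in% names(td)))
  H <- fit$model$params$hidden_size
  expect_identical(nrow(td[td$parameter == "Wg", ]), as.integer(4 * H * (H + 2)))
  gl <- glance(fit$model)
  expect_identical(nrow(gl), 1L)
  expect_lt(gl$final_loss, gl$initial_loss)
})
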
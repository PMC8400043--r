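#' One LSTM cell step (reference implementation)
#'
#' Pure-R evaluation of a single long short-term memory cell update over the
#' concatenated vector `[h_prev, x]`:
#' \deqn{f = \sigma(W_f [h, x] + b_f),\quad i = \sigma(W_i [h, x] + b_i),}
#' \deqn{\tilde C = \tanh(W_c [h, x] + b_c),\quad o = \sigma(W_o [h, x] + b_o),}
#' \deqn{c_t = f \circ c_{t-1} + i \circ \tilde C,\quad h_t = o \circ \tanh(c_t).}
#' This is the package's reference against which the compiled training path
#' is verified; it is also usable on its own for inspection.
#'
#' @param x Input vector (length `input_size`).
#' @param state List with `h` and `c`, each of length `hidden_size`.
#' @param params List with gate weight matrices `W_f`, `W_i`, `W_c`, `W_o`
#'   (each `hidden_size` x `(hidden_size + input_size)`, acting on
#'   `[h_prev, x]`) and biases `b_f`, `b_i`, `b_c`, `b_o`.
#' @return List with the new `h` and `c`.
#' @export
lstm_cell_step <- function(x, state, params) {
  sig <- function(z) 1 / (1 + exp(-z))
  h_prev <- state$h
  c_prev <- state$c
  hs <- length(h_prev)
  v <- c(h_prev, x)
  for (w in c("W_f", "W_i", "W_c", "W_o")) {
    if (!all(dim(params[[w]]) == c(hs, length(v)))) {
      abort_invalid(sprintf("`%s` must be %d x %d", w, hs, length(v)))
    }
  }
  f <- sig(drop(params$W_f %*% v) + params$b_f)
  i <- sig(drop(params$W_i %*% v) + params$b_i)
  cand <- tanh(drop(params$W_c %*% v) + params$b_c)
  o <- sig(drop(params$W_o %*% v) + params$b_o)
  c_t <- f * c_prev + i * cand
  list(h = o * tanh(c_t), c = c_t)
}

# Packed parameter initialization: Wg stacks gate blocks [i; f; g; o] over
# [h_prev; x]; Glorot-uniform scaled, forget-gate bias 1 (standard practice).
init_lstm_params <- function(input_size, hidden_size, output_size, seed) {
  set.seed(seed)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  H <- hidden_size
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1
  list(
    Wg = glorot(4 * H, H + input_size),
    b = b,
    Wy = glorot(output_size, H),
    by = numeric(output_size),
    input_size = input_size, hidden_size = H, output_size = output_size
  )
}

# Unpack Wg/b into the per-gate form used by lstm_cell_step().
unpack_gate_params <- function(p) {
  H <- p$hidden_size
  rows <- function(k) ((k - 1) * H + 1):(k * H)
  list(W_i = p$Wg[rows(1), , drop = FALSE], b_i = p$b[rows(1)],
       W_f = p$Wg[rows(2), , drop = FALSE], b_f = p$b[rows(2)],
       W_c = p$Wg[rows(3), , drop = FALSE], b_c = p$b[rows(3)],
       W_o = p$Wg[rows(4), , drop = FALSE], b_o = p$b[rows(4)])
}

#' Train the sequence-to-sequence flowrate regressor
#'
#' Fits a single-layer LSTM (default 5 hidden units) with a one-neuron dense
#' head on each hidden state to map per-frame (loudness, roughness) inputs to
#' the normalized flowrate, minimising mean-squared error with Adam and
#' backpropagation through time. Training is deterministic given `seed`.
#'
#' @param ts A regression [build_training_set()] result.
#' @param hidden_size Hidden units (default 5).
#' @param epochs Training epochs (default 40).
#' @param batch_size Sequences per parameter update (default 3).
#' @param learning_rate Adam step size (default 1e-3).
#' @param clip Global gradient-norm clip (default 5; 0 disables).
#' @param seed Integer seed for initialization and batch order (default 0).
#' @param features Input features to use: both (default) or
#'   `"roughness"` alone (the reduced single-input variant).
#' @return Object of class `uroflow_regressor`.
#' @export
train_flow_regressor <- function(ts, hidden_size = 5, epochs = 40,
                                 batch_size = 3, learning_rate = 1e-3,
                                 clip = 5, seed = 0,
                                 features = c("loudness", "roughness")) {
  stopifnot(inherits(ts, "uroflow_training_set"), ts$task == "regression")
  features <- match.arg(features, c("loudness", "roughness"),
                        several.ok = TRUE)
  if (length(ts$train) == 0L) abort_invalid("empty regression training set")
  xs <- purrr::map(ts$train, function(e) e$x[, features, drop = FALSE])
  ys <- purrr::map(ts$train, "y")
  p <- init_lstm_params(length(features), hidden_size, 1L, seed)
  fit <- cpp_train_regressor(xs, ys, p$Wg, p$b, p$Wy, p$by,
                             as.integer(epochs), as.integer(batch_size),
                             learning_rate, clip, as.integer(seed))
  structure(
    list(params = list(Wg = fit$Wg, b = as.numeric(fit$b), Wy = fit$Wy,
                       by = as.numeric(fit$by),
                       input_size = p$input_size, hidden_size = hidden_size,
                       output_size = 1L),
         features = features,
         scaling = ts$scaling,
         loss = as.numeric(fit$loss),
         config = list(hidden_size = hidden_size, epochs = epochs,
                       batch_size = batch_size,
                       learning_rate = learning_rate, clip = clip,
                       seed = seed),
         n_train = length(ts$train)),
    class = "uroflow_regressor"
  )
}

#' Predict a flowrate curve from sound features
#'
#' Runs the trained sequence-to-sequence LSTM over a feature series and
#' returns the de-standardized flowrate (mL/s, clipped at zero) on the
#' feature time grid.
#'
#' @param model A [train_flow_regressor()] fit.
#' @param features `feature_series` tibble (`time`, `loudness`, `roughness`).
#' @return A `uroflow_curve` tibble (`time`, `flow`).
#' @export
predict_flowrate <- function(model, features) {
  stopifnot(inherits(model, "uroflow_regressor"))
  if (nrow(features) == 0L) abort_invalid("empty feature series")
  sc <- model$scaling
  used <- model$features %||% c("loudness", "roughness")
  x <- vapply(used, function(f) {
    (features[[f]] - sc$x_mean[[f]]) / sc$x_sd[[f]]
  }, numeric(nrow(features)))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  fw <- cpp_lstm_forward(model$params$Wg, model$params$b, x)
  y <- drop(fw$h %*% t(model$params$Wy)) + model$params$by[1L]
  new_flow_tbl(features$time, pmax(y * sc$y_max, 0))
}

#' @export
predict.uroflow_regressor <- function(object, newdata, ...) {
  predict_flowrate(object, newdata)
}

#' Train the sequence-to-label pattern classifier
#'
#' Fits a single-layer LSTM (default 50 hidden units) over fixed-length
#' normalized flowrate sequences; the hidden state after the last step feeds
#' an affine softmax head over the three pattern classes. Cross-entropy is
#' minimised with Adam; deterministic given `seed`.
#'
#' @param ts A classification [build_training_set()] result.
#' @param hidden_size Hidden units (default 50).
#' @param epochs Training epochs (default 500; the desk-scale evaluations in
#'   this package use 50).
#' @param batch_size Sequences per update (default 3).
#' @param learning_rate Adam step size (default 1e-3).
#' @param clip Global gradient-norm clip (default 5).
#' @param seed Integer seed (default 0).
#' @return Object of class `uroflow_classifier`.
#' @export
train_pattern_classifier <- function(ts, hidden_size = 50, epochs = 500,
                                     batch_size = 3, learning_rate = 1e-3,
                                     clip = 5, seed = 0) {
  stopifnot(inherits(ts, "uroflow_training_set"), ts$task == "classification")
  if (length(ts$train) == 0L) abort_invalid("empty classification training set")
  classes <- c("A", "B", "C")
  labels <- vapply(ts$train, function(e) e$label, character(1))
  if (!all(classes %in% labels)) {
    abort_invalid("all three pattern classes must be present in training data")
  }
  X <- do.call(rbind, purrr::map(ts$train, "x"))
  p <- init_lstm_params(1L, hidden_size, length(classes), seed)
  fit <- cpp_train_classifier(X, as.integer(match(labels, classes) - 1L),
                              p$Wg, p$b, p$Wy, p$by,
                              as.integer(epochs), as.integer(batch_size),
                              learning_rate, clip, as.integer(seed))
  structure(
    list(params = list(Wg = fit$Wg, b = as.numeric(fit$b), Wy = fit$Wy,
                       by = as.numeric(fit$by),
                       input_size = 1L, hidden_size = hidden_size,
                       output_size = length(classes)),
         classes = classes,
         loss = as.numeric(fit$loss),
         config = list(hidden_size = hidden_size, epochs = epochs,
                       batch_size = batch_size,
                       learning_rate = learning_rate, clip = clip,
                       seed = seed),
         sequence_length = ncol(X),
         n_train = length(ts$train)),
    class = "uroflow_classifier"
  )
}

#' Classify a normalized flowrate sequence
#'
#' @param model A [train_pattern_classifier()] fit.
#' @param x A `uroflow_norm` tibble from [normalize_resample()], or a numeric
#'   vector, of the model's fixed sequence length.
#' @return One-row tibble with `label` (argmax class) and one probability
#'   column per class (`A`, `B`, `C`; nonnegative, summing to one).
#' @export
classify_pattern <- function(model, x) {
  stopifnot(inherits(model, "uroflow_classifier"))
  v <- if (is.data.frame(x)) x$flow else as.numeric(x)
  if (length(v) != model$sequence_length) {
    abort_invalid(sprintf("sequence must have length %d, got %d",
                          model$sequence_length, length(v)))
  }
  fw <- cpp_lstm_forward(model$params$Wg, model$params$b,
                         matrix(v, ncol = 1L))
  h_last <- fw$h[nrow(fw$h), ]
  logits <- drop(model$params$Wy %*% h_last) + model$params$by
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  out <- tibble(label = factor(model$classes[which.max(p)],
                               levels = model$classes))
  out[model$classes] <- as.list(p)
  out
}

#' Mean flowrate error rate between prediction and measurement
#'
#' Time-averaged absolute prediction error as a percentage of the maximum
#' measured flowrate:
#' \eqn{100 \cdot \mathrm{mean}_t |V_{pred}(t) - V_{meas}(t)| / \max_t V_{meas}(t)}.
#' If the two curves are on different grids the prediction is linearly
#' interpolated onto the measured grid over the overlap.
#'
#' @param pred,meas Flow tibbles (`time`, `flow`).
#' @return Error rate in percent.
#' @export
flow_error_rate <- function(pred, meas) {
  stopifnot(all(c("time", "flow") %in% names(pred)),
            all(c("time", "flow") %in% names(meas)))
  m_max <- max(meas$flow)
  if (!is.finite(m_max) || m_max <= 0) {
    abort_invalid("measured curve maximum must be positive")
  }
  keep <- meas$time >= min(pred$time) & meas$time <= max(pred$time)
  if (!any(keep)) abort_invalid("prediction and measurement do not overlap")
  p <- interp_linear(pred$time, pred$flow, meas$time[keep])
  100 * mean(abs(p - meas$flow[keep])) / m_max
}

#' Evaluate a regressor on the held-out events of a training set
#'
#' @param model A `uroflow_regressor`.
#' @param ts The regression `uroflow_training_set` it was trained on.
#' @return Tibble with one row per validation event: `patient` and
#'   `error_rate` (percent of the measured maximum).
#' @export
evaluate_flow_predictions <- function(model, ts) {
  stopifnot(inherits(ts, "uroflow_training_set"), ts$task == "regression")
  sc <- ts$scaling
  purrr::map_dfr(ts$validation, function(e) {
    feats <- new_feature_tbl(
      time = e$time,
      loudness = e$x[, 1L] * sc$x_sd[["loudness"]] + sc$x_mean[["loudness"]],
      roughness = e$x[, 2L] * sc$x_sd[["roughness"]] + sc$x_mean[["roughness"]]
    )
    pred <- predict_flowrate(model, feats)
    meas <- new_flow_tbl(e$time, e$y * sc$y_max)
    tibble(patient = e$patient, error_rate = flow_error_rate(pred, meas))
  })
}

#' Evaluate a classifier on the held-out sequences of a training set
#'
#' @param model A `uroflow_classifier`.
#' @param ts The classification `uroflow_training_set` it was trained on.
#' @return Tibble with one row per validation sequence: `patient`, `label`
#'   (true), `predicted`, and `p_true`, the softmax probability assigned to
#'   the true class.
#' @export
evaluate_classifications <- function(model, ts) {
  stopifnot(inherits(ts, "uroflow_training_set"), ts$task == "classification")
  purrr::map_dfr(ts$validation, function(e) {
    res <- classify_pattern(model, e$x)
    tibble(patient = e$patient, label = e$label,
           predicted = as.character(res$label),
           p_true = res[[e$label]])
  })
}

#' @export
print.uroflow_regressor <- function(x, ...) {
  cat(sprintf("<uroflow_regressor: %d->%d LSTM + 1-unit head, %d epochs, final MSE %.4g>\n",
              x$params$input_size, x$params$hidden_size, x$config$epochs,
              x$loss[length(x$loss)]))
  invisible(x)
}

#' @export
print.uroflow_classifier <- function(x, ...) {
  cat(sprintf("<uroflow_classifier: %d-unit LSTM -> %d classes, %d epochs, final CE %.4g>\n",
              x$params$hidden_size, x$params$output_size, x$config$epochs,
              x$loss[length(x$loss)]))
  invisible(x)
}

tidy_lstm_params <- function(p) {
  one <- function(name, w) {
    w <- as.matrix(w)
    tibble(parameter = name,
           row = rep(seq_len(nrow(w)), times = ncol(w)),
           col = rep(seq_len(ncol(w)), each = nrow(w)),
           value = as.numeric(w))
  }
  dplyr::bind_rows(one("Wg", p$Wg), one("b", matrix(p$b, ncol = 1)),
                   one("Wy", p$Wy), one("by", matrix(p$by, ncol = 1)))
}

#' Broom-style tidiers for fitted models
#'
#' `tidy()` returns one row per parameter entry; `glance()` returns a
#' one-row model summary.
#'
#' @param x A `uroflow_regressor` or `uroflow_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.uroflow_regressor <- function(x, ...) tidy_lstm_params(x$params)

#' @rdname tidy.uroflow_regressor
#' @export
tidy.uroflow_classifier <- function(x, ...) tidy_lstm_params(x$params)

#' @rdname tidy.uroflow_regressor
#' @export
glance.uroflow_regressor <- function(x, ...) {
  tibble(hidden_size = x$params$hidden_size,
         input_size = x$params$input_size,
         epochs = x$config$epochs, batch_size = x$config$batch_size,
         learning_rate = x$config$learning_rate, seed = x$config$seed,
         n_train = x$n_train,
         initial_loss = x$loss[1L], final_loss = x$loss[length(x$loss)])
}

#' @rdname tidy.uroflow_regressor
#' @export
glance.uroflow_classifier <- function(x, ...) {
  tibble(hidden_size = x$params$hidden_size, n_classes = x$params$output_size,
         sequence_length = x$sequence_length,
         epochs = x$config$epochs, batch_size = x$config$batch_size,
         learning_rate = x$config$learning_rate, seed = x$config$seed,
         n_train = x$n_train,
         initial_loss = x$loss[1L], final_loss = x$loss[length(x$loss)])
}

#' Save / load a fitted model as versioned JSON
#'
#' Weights are stored as full-precision JSON arrays together with the model
#' type, configuration and scaling, so models round-trip exactly on any
#' platform.
#'
#' @param model A `uroflow_regressor` or `uroflow_classifier`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the model object.
#' @export
write_model <- function(model, path) {
  type <- class(model)[1L]
  stopifnot(type %in% c("uroflow_regressor", "uroflow_classifier"))
  payload <- list(
    format = "sonouroflow-model", version = 1L, type = type,
    params = list(Wg = model$params$Wg, b = model$params$b,
                  Wy = model$params$Wy, by = model$params$by,
                  input_size = model$params$input_size,
                  hidden_size = model$params$hidden_size,
                  output_size = model$params$output_size),
    scaling = if (!is.null(model$scaling)) {
      list(x_mean = as.list(model$scaling$x_mean),
           x_sd = as.list(model$scaling$x_sd),
           y_max = model$scaling$y_max)
    },
    classes = model$classes,
    features = model$features,
    sequence_length = model$sequence_length,
    config = model$config, loss = model$loss, n_train = model$n_train
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "sonouroflow-model")) {
    abort_invalid("not a sonouroflow model file")
  }
  params <- list(Wg = as.matrix(p$params$Wg), b = as.numeric(p$params$b),
                 Wy = as.matrix(p$params$Wy),
                 by = as.numeric(p$params$by),
                 input_size = p$params$input_size,
                 hidden_size = p$params$hidden_size,
                 output_size = p$params$output_size)
  if (p$type == "uroflow_regressor") {
    sc <- p$scaling
    structure(list(params = params,
                   features = p$features,
                   scaling = list(x_mean = unlist(sc$x_mean),
                                  x_sd = unlist(sc$x_sd), y_max = sc$y_max),
                   loss = p$loss, config = p$config, n_train = p$n_train),
              class = "uroflow_regressor")
  } else {
    structure(list(params = params, classes = p$classes, loss = p$loss,
                   config = p$config, sequence_length = p$sequence_length,
                   n_train = p$n_train),
              class = "uroflow_classifier")
  }
}
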
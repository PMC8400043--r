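#' Align a feature series with a flowrate curve on a common grid
#'
#' Both series are linearly interpolated onto one uniform grid spanning the
#' intersection of their time supports, at the coarser of the two native
#' sampling rates.
#'
#' @param features `feature_series` tibble (`time`, `loudness`, `roughness`).
#' @param flow Flow tibble (`time`, `flow`).
#' @return Tibble with columns `time`, `loudness`, `roughness`, `flow`.
#' @export
align_features_to_flow <- function(features, flow) {
  stopifnot(all(c("time", "loudness", "roughness") %in% names(features)),
            all(c("time", "flow") %in% names(flow)))
  t0 <- max(min(features$time), min(flow$time))
  t1 <- min(max(features$time), max(flow$time))
  if (t1 <= t0) abort_invalid("feature and flow time supports are disjoint")
  dt_f <- stats::median(diff(features$time))
  dt_q <- stats::median(diff(flow$time))
  dt <- max(dt_f, dt_q)
  grid <- seq(t0, t1, by = dt)
  tibble(
    time = grid,
    loudness = interp_linear(features$time, features$loudness, grid),
    roughness = interp_linear(features$time, features$roughness, grid),
    flow = interp_linear(flow$time, flow$flow, grid)
  )
}

#' Normalize and resample a flowrate curve to a fixed length
#'
#' Maps time onto `[0, 1]`, linearly interpolates to exactly `length` points
#' (default 246), and divides values by the resampled maximum so the peak is
#' exactly one. The original scale is stored in the `source_scale` attribute
#' so the transform is invertible via [denormalize_sequence()].
#'
#' @param flow Flow tibble (`time`, `flow`) with at least 2 samples and a
#'   positive maximum.
#' @param length Number of output samples (default 246).
#' @return Tibble (`time` in `[0, 1]`, `flow` in `[0, 1]`) of class
#'   `uroflow_norm`, with attribute `source_scale = c(t_min, t_max, v_max)`.
#' @export
normalize_resample <- function(flow, length = 246) {
  stopifnot(all(c("time", "flow") %in% names(flow)))
  if (nrow(flow) < 2L) abort_invalid("need at least 2 samples to resample")
  assert_times(flow$time)
  v_max <- max(flow$flow)
  if (!is.finite(v_max) || v_max <= 0) {
    abort_invalid("curve maximum must be positive to normalize")
  }
  t_min <- flow$time[1L]
  t_max <- flow$time[nrow(flow)]
  u <- (flow$time - t_min) / (t_max - t_min)
  grid <- seq(0, 1, length.out = as.integer(length))
  vals <- interp_linear(u, flow$flow, grid)
  # scale by the resampled maximum so the output peak is exactly 1 and the
  # transform is idempotent; the stored v_max still inverts it
  v_max <- max(vals)
  out <- tibble(time = grid, flow = vals / v_max)
  attr(out, "source_scale") <- c(t_min = t_min, t_max = t_max, v_max = v_max)
  class(out) <- c("uroflow_norm", class(out))
  out
}

#' Invert [normalize_resample()]
#'
#' @param x A `uroflow_norm` tibble carrying a `source_scale` attribute.
#' @return A `uroflow_curve` tibble on the original time and flow scales.
#' @export
denormalize_sequence <- function(x) {
  sc <- attr(x, "source_scale")
  if (is.null(sc)) abort_invalid("`x` carries no source_scale attribute")
  new_flow_tbl(sc[["t_min"]] + x$time * (sc[["t_max"]] - sc[["t_min"]]),
               x$flow * sc[["v_max"]])
}

#' Augment a flowrate curve with bounded random perturbations
#'
#' Generates `n_copies` perturbed curves \eqn{V'(t) = |V(t) + A\,\mathrm{rand}(t)|}
#' with `rand` i.i.d. uniform on `[-1, 1]` per sample and the amplitude `A`
#' drawn per copy uniformly from `(0, amplitude_fraction * max(V))`. The
#' perturbation is therefore bounded by 5% of the peak flowrate under the
#' default fraction, small enough to preserve the clinical pattern label.
#'
#' @param flow Flow tibble (`time`, `flow`) with positive maximum.
#' @param n_copies Number of copies (default 100).
#' @param amplitude_fraction Upper bound on `A` as a fraction of the curve
#'   maximum (default 0.05).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return Long tibble with columns `copy`, `time`, `flow`.
#' @export
augment_flow <- function(flow, n_copies = 100, amplitude_fraction = 0.05,
                         seed = NULL) {
  stopifnot(all(c("time", "flow") %in% names(flow)))
  assert_scalar_number(n_copies, "n_copies", lower = 1)
  assert_scalar_number(amplitude_fraction, "amplitude_fraction",
                       lower = 0, upper = 0.05)
  v_max <- max(flow$flow)
  if (!is.finite(v_max) || v_max <= 0) {
    abort_invalid("curve maximum must be positive to augment")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(flow)
  n_copies <- as.integer(n_copies)
  # one amplitude draw per copy, then i.i.d. uniform jitter per sample
  out <- vector("list", n_copies)
  for (k in seq_len(n_copies)) {
    a <- runif(1, 0, amplitude_fraction * v_max)
    out[[k]] <- abs(flow$flow + a * runif(n, -1, 1))
  }
  tibble(copy = rep(seq_len(n_copies), each = n),
         time = rep(flow$time, times = n_copies),
         flow = unlist(out))
}

# Stratified patient-wise split: per class, round(split_fraction * n) patients
# go to train (at least 1 in each side when the class has >= 2 patients).
split_patients <- function(patients, labels, split_fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  train <- character(0)
  for (cl in unique(as.character(labels))) {
    p <- patients[as.character(labels) == cl]
    n_tr <- round(split_fraction * length(p))
    if (length(p) >= 2L) n_tr <- min(max(n_tr, 1L), length(p) - 1L)
    train <- c(train, sample(p, n_tr))
  }
  train
}

#' Assemble a training set from a synthetic or measured cohort
#'
#' Splits patients (never individual curves) into train and validation sets,
#' then builds task-specific examples:
#' * `task = "classification"`: each patient's flow curve is augmented with
#'   `n_copies` bounded perturbations, every copy is normalized and resampled
#'   to `length` points, and the target is the patient's pattern label.
#' * `task = "regression"`: each patient's feature series is aligned with its
#'   flow curve; the two input features are z-scored using train-set
#'   statistics only and the target flowrate is scaled by the train-set
#'   maximum (no information from validation patients leaks into the scaling).
#'
#' @param cohort Tibble with columns `patient`, `label`, and list-columns
#'   `flow` (and `features` for regression), e.g. from [gen_cohort()].
#' @param task `"classification"` or `"regression"`.
#' @param split_fraction Fraction of patients per class assigned to training
#'   (default 0.8).
#' @param n_copies Augmented copies per patient for classification
#'   (default 100).
#' @param length Resampled sequence length for classification (default 246).
#' @param seed Integer seed driving the split and augmentation (default 0).
#' @return A list of class `uroflow_training_set`: `task`, `train`,
#'   `validation` (lists of examples), `scaling`, `seed`. Classification
#'   examples are `list(x = length-vector, label, patient)`; regression
#'   examples are `list(x = T x 2 matrix, y = length-T target, time, patient)`.
#' @export
build_training_set <- function(cohort, task = c("classification", "regression"),
                               split_fraction = 0.8, n_copies = 100,
                               length = 246, seed = 0) {
  task <- match.arg(task)
  stopifnot(all(c("patient", "label", "flow") %in% names(cohort)))
  if (nrow(cohort) < 2L) abort_invalid("need at least 2 patients to split")
  set.seed(seed)
  train_ids <- split_patients(cohort$patient, cohort$label, split_fraction)
  is_train <- cohort$patient %in% train_ids

  if (task == "classification") {
    if (dplyr::n_distinct(cohort$label[is_train]) < 2L) {
      abort_invalid("training split must contain more than one class")
    }
    make_examples <- function(rows) {
      purrr::flatten(purrr::map(rows, function(i) {
        copies <- augment_flow(cohort$flow[[i]], n_copies = n_copies,
                               seed = NULL)
        purrr::map(split(copies, copies$copy), function(cp) {
          ns <- normalize_resample(cp[c("time", "flow")], length = length)
          list(x = ns$flow, label = as.character(cohort$label[i]),
               patient = cohort$patient[i])
        })
      }))
    }
    train <- make_examples(which(is_train))
    validation <- make_examples(which(!is_train))
    scaling <- list(length = length)
  } else {
    stopifnot("features" %in% names(cohort))
    aligned <- purrr::map(seq_len(nrow(cohort)), function(i) {
      align_features_to_flow(cohort$features[[i]], cohort$flow[[i]])
    })
    xs_train <- dplyr::bind_rows(aligned[is_train])
    scaling <- list(
      x_mean = c(loudness = mean(xs_train$loudness),
                 roughness = mean(xs_train$roughness)),
      x_sd = c(loudness = max(sd(xs_train$loudness), 1e-12),
               roughness = max(sd(xs_train$roughness), 1e-12)),
      y_max = max(xs_train$flow)
    )
    if (scaling$y_max <= 0) abort_invalid("train flowrates are all zero")
    make_example <- function(i) {
      al <- aligned[[i]]
      x <- cbind(
        loudness = (al$loudness - scaling$x_mean[["loudness"]]) / scaling$x_sd[["loudness"]],
        roughness = (al$roughness - scaling$x_mean[["roughness"]]) / scaling$x_sd[["roughness"]]
      )
      list(x = x, y = al$flow / scaling$y_max, time = al$time,
           patient = cohort$patient[i])
    }
    train <- purrr::map(which(is_train), make_example)
    validation <- purrr::map(which(!is_train), make_example)
  }

  structure(list(task = task, train = train, validation = validation,
                 scaling = scaling, seed = seed,
                 train_patients = sort(unique(cohort$patient[is_train])),
                 validation_patients = sort(unique(cohort$patient[!is_train]))),
            class = "uroflow_training_set")
}

#' @export
print.uroflow_training_set <- function(x, ...) {
  cat(sprintf("<uroflow_training_set: %s, %d train / %d validation examples, %d/%d patients>\n",
              x$task, length(x$train), length(x$validation),
              length(x$train_patients), length(x$validation_patients)))
  invisible(x)
}
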
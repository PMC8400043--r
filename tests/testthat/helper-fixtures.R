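# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Small labelled cohort (4 patients per class).
small_cohort <- function() {
  cached("small_cohort", gen_cohort(n_per_class = 4, seed = 11))
}

# A quick regression fit on the small cohort.
small_regressor <- function() {
  cached("small_regressor", {
    ts <- build_training_set(small_cohort(), task = "regression",
                             split_fraction = 0.75, seed = 11)
    list(ts = ts, model = train_flow_regressor(ts, epochs = 25, seed = 11))
  })
}

# Random packed LSTM parameters for oracle comparisons.
random_packed_params <- function(input_size, hidden_size) {
  H <- hidden_size
  list(Wg = matrix(rnorm(4 * H * (H + input_size), sd = 0.5),
                   4 * H, H + input_size),
       b = rnorm(4 * H, sd = 0.5),
       input_size = input_size, hidden_size = H)
}

# Manually built zero-weight classifier (three classes, length-n sequences).
zero_classifier <- function(hidden_size = 4, seq_len = 246) {
  structure(
    list(params = list(Wg = matrix(0, 4 * hidden_size, hidden_size + 1),
                       b = numeric(4 * hidden_size),
                       Wy = matrix(0, 3, hidden_size), by = numeric(3),
                       input_size = 1L, hidden_size = hidden_size,
                       output_size = 3L),
         classes = c("A", "B", "C"),
         loss = NA_real_, config = list(), sequence_length = seq_len,
         n_train = 0L),
    class = "uroflow_classifier"
  )
}

# Bark excitation object with prescribed values (for direct formula checks).
manual_excitation <- function(bark, excitation, threshold) {
  structure(list(bark = bark, excitation = excitation, threshold = threshold),
            class = "bark_excitation")
}
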
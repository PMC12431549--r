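# Shared fixtures, built in code at test time.

# A tiny linear-friendly spec for fast engine tests.
tiny_spec <- function(input_len = 100L, n_classes = 2L, filters = 4L,
                      kernel = 5L, dense_units = 8L, dropout = 0) {
  model_spec("tiny", input_len, 1L,
             list(layer_conv1d(filters, kernel, "same", "relu"),
                  layer_maxpool1d(2L, 2L),
                  layer_flatten(),
                  layer_dropout(dropout),
                  layer_dense(dense_units, "relu"),
                  layer_dense(n_classes, "none"),
                  layer_softmax()),
             n_classes)
}

# A small separable two-class window set (class 0: low-frequency sine,
# class 1: spiky), for overfit/determinism tests.
toy_window_set <- function(n_per_class = 10L, len = 100L, seed = 7L) {
  set.seed(seed)
  t <- seq_len(len) / len
  rows <- list()
  labs <- numeric(0)
  for (i in seq_len(n_per_class)) {
    rows[[length(rows) + 1L]] <- sin(2 * pi * 3 * t + runif(1)) +
      rnorm(len, 0, 0.05)
    labs <- c(labs, 0)
  }
  for (i in seq_len(n_per_class)) {
    x <- rnorm(len, 0, 0.05)
    x[sample(10:90, 4)] <- 3
    rows[[length(rows) + 1L]] <- x
    labs <- c(labs, 1)
  }
  enc <- encode_labels(ifelse(labs == 0, "Normal", "Arrhythmia"), "binary")
  window_set(do.call(rbind, rows), enc$onehot,
             sprintf("T%02d", seq_along(labs)), enc$class_order)
}

# Small preprocessed binary cohort shared by slow tests (memoised per run).
.cohort_cache <- new.env(parent = emptyenv())
smoke_window_set <- function() {
  if (is.null(.cohort_cache$ws)) {
    co <- synth_cohort(8, c(NSR = 0.5, AF = 0.5),
                       synth_config(duration_s = 64), seed = 42)
    .cohort_cache$cohort <- co
    .cohort_cache$ws <- run_preprocessing(cohort_segment_table(co),
                                          preprocess_config(),
                                          mode = "binary")
  }
  .cohort_cache$ws
}
smoke_cohort <- function() {
  smoke_window_set()
  .cohort_cache$cohort
}
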
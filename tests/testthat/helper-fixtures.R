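# Shared fixtures. Everything is generated in code at test time; the
# expensive trained smoke model is built once per session and cached.

tiny_model_config <- function(dropout = 0, init_seed = 7L) {
  model_config(
    epoch_len = 40L, n_epochs = 12L, attention_channels = 3L,
    stem_channels = 4L, stem_kernel = 8L, stem_stride = 4L,
    inception_in = c(4L, 4L), inception_filters = c(1L, 2L),
    inception_bottleneck = c(2L, 2L), inception_kernels = c(3L, 5L, 7L),
    post_channels = 6L, tdd_width = 5L,
    tcn_blocks = 2L, tcn_channels = 8L, tcn_kernel = 3L,
    tcn_dilations = c(1L, 2L), tcn_dropout = dropout, init_seed = init_seed)
}

random_epochized <- function(config, n_valid = config$n_epochs, seed = 1) {
  set.seed(seed)
  v <- matrix(runif(config$n_epochs * config$epoch_len),
              config$n_epochs, config$epoch_len)
  if (n_valid < config$n_epochs) v[(n_valid + 1):config$n_epochs, ] <- 0
  epochized_input(v, n_valid)
}

random_labels <- function(n, seed = 1, n_valid = n) {
  set.seed(seed)
  y <- sample(0:3, n, replace = TRUE)
  mask <- seq_len(n) <= n_valid
  y[!mask] <- NA_integer_
  four_class_labels(y, mask)
}

# Closed-form parameter count, independent of the builder's bookkeeping.
expected_param_count <- function(cfg) {
  ca <- cfg$attention_channels
  total <- cfg$attention_kernel * ca + ca +  # causal conv
    ca + 1 +                                 # 1x1 projection
    cfg$stem_kernel * cfg$stem_channels + cfg$stem_channels
  for (b in seq_along(cfg$inception_in)) {
    ic <- cfg$inception_in[b]
    f <- cfg$inception_filters[b]
    bo <- cfg$inception_bottleneck[b]
    oc <- 4 * f
    total <- total + (ic * bo + bo) +
      sum(cfg$inception_kernels) * bo * f + 3 * f +
      (ic * f + f) +           # max-pool projection
      2 * oc +                 # batch norm
      (ic * oc + oc) + 2 * oc  # residual conv + its batch norm
  }
  oc_last <- 4 * cfg$inception_filters[length(cfg$inception_filters)]
  total <- total + oc_last * cfg$post_channels + cfg$post_channels +
    cfg$post_channels * cfg$tdd_width + cfg$tdd_width
  in_ch <- cfg$tdd_width
  for (j in seq_len(cfg$tcn_blocks)) {
    total <- total + cfg$tcn_channels * in_ch * cfg$tcn_kernel +
      cfg$tcn_channels * cfg$tcn_channels * cfg$tcn_kernel
    if (in_ch != cfg$tcn_channels) {
      total <- total + in_ch * cfg$tcn_channels + cfg$tcn_channels
    }
    in_ch <- cfg$tcn_channels
  }
  total + cfg$tcn_channels * cfg$n_classes + cfg$n_classes
}

# Smoke-scale end-to-end fixture: 16 one-hour synthetic nights, reduced
# model trained 20 epochs on 12 of them. Cached across tests.
smoke_env <- new.env(parent = emptyenv())

smoke_fixture <- function() {
  if (!is.null(smoke_env$fit)) return(as.list(smoke_env))
  dir <- file.path(tempdir(), "insightsleep-smoke")
  cfg <- synth_config(n_subjects = 16L, duration_hours = 1, fs = 128L,
                      seed = 11L)
  manifest <- make_dataset(cfg, dir)
  data <- load_dataset(manifest, n_epochs = 120L)
  model <- build_model(reduced_model_config(n_epochs = 120L, init_seed = 3L))
  fit <- train_loop(model, data[1:12],
                    train_config(optimizer = "adam", lr = 0.001,
                                 batch_size = 2L, max_epochs = 20L,
                                 seed = 5L))
  smoke_env$data <- data
  smoke_env$train_idx <- 1:12
  smoke_env$test_idx <- 13:16
  smoke_env$fit <- fit
  as.list(smoke_env)
}
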
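test_that("the default configuration has exactly the published parameter count", {
  m <- build_model(model_config())
  expect_identical(count_trainable_parameters(m), 1922397)
})

test_that("parameter count is a pure function of the configuration", {
  for (cfg in list(tiny_model_config(), reduced_model_config(),
                   model_config())) {
    m1 <- build_model(cfg)
    expect_equal(count_trainable_parameters(m1), expected_param_count(cfg))
    cfg2 <- cfg
    cfg2$init_seed <- cfg$init_seed + 100L
    expect_equal(count_trainable_parameters(build_model(cfg2)),
                 count_trainable_parameters(m1))
  }
})

test_that("parameter count is additive over modules", {
  cfg_a <- tiny_model_config()
  cfg_b <- tiny_model_config()
  cfg_b$attention_channels <- cfg_a$attention_channels + 2L
  # widening the attention conv by c channels adds c*(K+2) parameters
  delta <- 2L * (cfg_a$attention_kernel + 2L)
  expect_equal(count_trainable_parameters(build_model(cfg_b)) -
                 count_trainable_parameters(build_model(cfg_a)), delta)
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(inception_filters = c(8L, 9L, 16L, 32L, 64L,
                                                  128L)),
               "channel chain")
  expect_error(model_config(tcn_dilations = c(1L, 2L, 4L, 8L, 15L)),
               "double")
  expect_error(model_config(inception_bottleneck = c(8L, 16L)), "length")
})

test_that("forward maps the grid to (n_epochs, n_classes) with softmax rows", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  out <- insight_forward(m, random_epochized(cfg))
  expect_identical(dim(out$logits), c(cfg$n_epochs, 4L))
  expect_identical(dim(out$probs), c(cfg$n_epochs, 4L))
  expect_equal(rowSums(out$probs), rep(1, cfg$n_epochs), tolerance = 1e-6)
  expect_true(all(out$probs >= 0 & out$probs <= 1))

  zero <- insight_forward(m, matrix(0, cfg$n_epochs, cfg$epoch_len))
  expect_true(all(is.finite(zero$logits)))
  expect_equal(rowSums(zero$probs), rep(1, cfg$n_epochs), tolerance = 1e-6)

  cfg2 <- tiny_model_config()
  cfg2$n_classes <- 2L
  out2 <- insight_forward(build_model(cfg2), random_epochized(cfg2))
  expect_identical(dim(out2$logits), c(cfg2$n_epochs, 2L))
})

test_that("eval-mode forward passes are deterministic and padded epochs produce logits", {
  cfg <- tiny_model_config(dropout = 0.2)
  m <- build_model(cfg)
  x <- random_epochized(cfg, n_valid = 8L)
  a <- insight_forward(m, x)
  b <- insight_forward(m, x)
  expect_identical(a$logits, b$logits)
  expect_true(all(is.finite(a$logits)))  # padded rows still populated
})

test_that("checkpoints round-trip eval-mode logits exactly", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  x <- random_epochized(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(insight_forward(m, x)$logits,
                   insight_forward(m2, x)$logits)
  expect_error(load_checkpoint(file.path(tempdir(), "none.rds")),
               "not found")
})

test_that("attention scores are sigmoid-bounded and strictly causal", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  set.seed(21)
  x <- runif(cfg$n_epochs * cfg$epoch_len)
  att <- local_attention_forward(m, x)
  expect_true(all(att$attention > 0 & att$attention < 1))
  expect_equal(att$weighted, x * att$attention)

  # perturbing epoch e+2 leaves attention within epochs <= e unchanged
  e <- 5L
  len <- cfg$epoch_len
  x2 <- x
  x2[((e + 1L) * len + 1):((e + 2L) * len)] <- runif(len)
  att2 <- local_attention_forward(m, x2)
  expect_lt(max(abs(att2$attention[1:(e * len)] -
                      att$attention[1:(e * len)])), 1e-6)
  expect_gt(max(abs(att2$attention - att$attention)), 0)
})

test_that("the attention receptive field spans exactly seven epochs", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  set.seed(22)
  len <- cfg$epoch_len
  x <- runif(cfg$n_epochs * len)
  base <- local_attention_forward(m, x)$attention
  cur <- 10L  # probe attention inside epoch 10
  cur_idx <- ((cur - 1L) * len + 1):(cur * len)
  perturb_epoch <- function(ep) {
    x2 <- x
    x2[((ep - 1L) * len + 1):(ep * len)] <- runif(len)
    local_attention_forward(m, x2)$attention
  }
  # 8 epochs in the past: outside the 7-epoch kernel, no change
  expect_lt(max(abs(perturb_epoch(cur - 8L)[cur_idx] - base[cur_idx])), 1e-9)
  # 6 epochs in the past: inside the kernel, visible change
  expect_gt(max(abs(perturb_epoch(cur - 6L)[cur_idx] - base[cur_idx])), 1e-9)
})

test_that("the temporal stack is strictly causal at epoch resolution", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  set.seed(23)
  feats <- matrix(rnorm(cfg$tdd_width * cfg$n_epochs), cfg$tdd_width)
  base <- temporal_stack_forward(m, feats)
  e <- 6L
  feats2 <- feats
  feats2[, e + 1L] <- rnorm(cfg$tdd_width)
  out2 <- temporal_stack_forward(m, feats2)
  expect_lt(max(abs(out2[, 1:e] - base[, 1:e])), 1e-6)
  expect_gt(max(abs(out2 - base)), 0)
})

test_that("the temporal stack receptive field follows the dilation arithmetic", {
  # default: 1 + (8-1)*2*(1+2+4+8+16) = 435 epochs
  cfg <- model_config()
  expect_equal(1 + (cfg$tcn_kernel - 1) * 2 * sum(cfg$tcn_dilations), 435)
  # verified by perturbation on a tiny config: RF = 1 + (3-1)*2*(1+2) = 13
  tcfg <- model_config(
    epoch_len = 40L, n_epochs = 20L, attention_channels = 3L,
    stem_channels = 4L, stem_kernel = 8L, stem_stride = 4L,
    inception_in = c(4L, 4L), inception_filters = c(1L, 2L),
    inception_bottleneck = c(2L, 2L), inception_kernels = c(3L, 5L, 7L),
    post_channels = 6L, tdd_width = 5L,
    tcn_blocks = 2L, tcn_channels = 8L, tcn_kernel = 3L,
    tcn_dilations = c(1L, 2L), tcn_dropout = 0, init_seed = 7L)
  rf <- 1 + (tcfg$tcn_kernel - 1) * 2 * sum(tcfg$tcn_dilations)
  m <- build_model(tcfg)
  set.seed(24)
  n <- tcfg$n_epochs
  feats <- matrix(rnorm(tcfg$tdd_width * n), tcfg$tdd_width)
  base <- temporal_stack_forward(m, feats)
  probe <- n  # last epoch
  feats_far <- feats
  feats_far[, probe - rf] <- rnorm(tcfg$tdd_width)  # outside RF
  expect_lt(max(abs(temporal_stack_forward(m, feats_far)[, probe] -
                      base[, probe])), 1e-9)
  feats_near <- feats
  feats_near[, probe - rf + 1L] <- rnorm(tcfg$tdd_width) * 5  # boundary
  expect_gt(max(abs(temporal_stack_forward(m, feats_near)[, probe] -
                      base[, probe])), 0)
})

test_that("the Inception module emits the epoch-length grid and is shift-equivariant", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  set.seed(25)
  xw <- runif(cfg$n_epochs * cfg$epoch_len)
  feats <- inception_module_forward(m, xw)
  expect_identical(dim(feats), c(cfg$post_channels, cfg$n_epochs))

  # all-zero input propagates a constant (bias-driven) feature map away
  # from the zero-padded borders
  zfeat <- inception_module_forward(m, numeric(cfg$n_epochs * cfg$epoch_len))
  interior <- 3:(cfg$n_epochs - 2L)
  expect_lt(max(abs(zfeat[, interior] - zfeat[, interior[1]])), 1e-9)

  # a stem-stride shift of the input shifts the pre-pooling features by one
  shifted <- c(xw[(cfg$stem_stride + 1):length(xw)],
               xw[1:cfg$stem_stride])
  pre_a <- insightsleep:::inception_component(m, xw, FALSE,
                                              m$buffers, keep_prepool = TRUE)
  pre_b <- insightsleep:::inception_component(m, shifted, FALSE,
                                              m$buffers, keep_prepool = TRUE)
  La <- ncol(pre_a$prepool)
  interior <- 30:(La - 30)
  expect_lt(max(abs(pre_b$prepool[, interior] -
                      pre_a$prepool[, interior + 1L])), 1e-8)
})

test_that("block output channels are four times the branch filters", {
  cfg <- reduced_model_config()
  m <- build_model(cfg)
  for (b in seq_along(cfg$inception_filters)) {
    expect_length(m$params[[paste0("inc", b, "_bn")]]$gamma,
                  4L * cfg$inception_filters[b])
  }
})

test_that("logits are causally bounded end to end at epoch resolution", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  set.seed(26)
  x <- matrix(runif(cfg$n_epochs * cfg$epoch_len), cfg$n_epochs)
  base <- insight_forward(m, x)$logits
  e <- 4L
  x2 <- x
  x2[e + 3L, ] <- runif(cfg$epoch_len)  # beyond the inception look-ahead
  out2 <- insight_forward(m, x2)$logits
  expect_lt(max(abs(out2[1:e, ] - base[1:e, ])), 1e-8)
  expect_gt(max(abs(out2 - base)), 0)
})

test_that("extract_attention aggregates per epoch and normalizes the valid span", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  x <- random_epochized(cfg, n_valid = 9L, seed = 31)
  am <- extract_attention(m, x)
  expect_length(am$per_epoch, cfg$n_epochs)
  expect_length(am$per_sample, cfg$n_epochs * cfg$epoch_len)
  valid <- seq_len(9L * cfg$epoch_len)
  expect_equal(range(am$normalized[valid]), c(0, 1))
  expect_equal(am$per_epoch[1],
               mean(am$per_sample[1:cfg$epoch_len]))
})

test_that("attention concentrates differently on pulse peaks than troughs", {
  # reported association, not a directional claim
  sp <- DEFAULT_STAGE_PARAMS
  sp$cv[] <- 0
  cfg_s <- synth_config(seed = 2, stage_params = sp, noise_sd = 0,
                        wander_amplitude = 0)
  hyp <- generate_hypnogram(cfg_s, 10L)
  rec <- generate_ppg(hyp, cfg_s)
  mcfg <- reduced_model_config(n_epochs = 10L)
  ep <- preprocess_pipeline(rec, n_epochs = 10L)
  m <- build_model(mcfg)
  am <- extract_attention(m, ep)
  scale <- (1024 / 30) / cfg_s$fs
  peaks_new <- pmax(1L, pmin(length(am$per_sample),
                             round(rec$peaks * scale)))
  troughs <- setdiff(seq_along(am$per_sample), peaks_new)
  diff_means <- mean(am$per_sample[peaks_new]) - mean(am$per_sample[troughs])
  expect_true(is.finite(diff_means))
})
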
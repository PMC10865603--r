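test_that("masked weighted NLL matches hand evaluation", {
  # perfect one-hot predictions -> zero loss
  lp <- log(matrix(c(1, 0, 0, 0,
                     0, 1, 0, 0) + 1e-300, 2, byrow = TRUE))
  labs <- four_class_labels(c(0L, 1L))
  expect_lt(masked_weighted_nll(lp, labs), 1e-6)

  # uniform p = 0.25, unit weights -> log 4
  lp_u <- matrix(log(0.25), 2, 4)
  expect_equal(masked_weighted_nll(lp_u, labs), log(4), tolerance = 1e-12)

  # weighted mean normalization: sum w_y nll / sum w_y
  lp2 <- log(rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25)))
  w <- c(2, 1, 1, 1)
  expected <- (2 * -log(0.7) + 1 * -log(0.25)) / (2 + 1)
  expect_equal(masked_weighted_nll(lp2, four_class_labels(c(0L, 1L)), w),
               expected, tolerance = 1e-12)

  # masked-out labels are inert, bit for bit
  labs3 <- four_class_labels(c(0L, 1L, 2L), c(TRUE, TRUE, FALSE))
  labs4 <- four_class_labels(c(0L, 1L, 3L), c(TRUE, TRUE, FALSE))
  lp3 <- log(matrix(0.25, 3, 4))
  expect_identical(masked_weighted_nll(lp3, labs3),
                   masked_weighted_nll(lp3, labs4))
  expect_error(masked_weighted_nll(lp3,
                                   four_class_labels(rep(NA_integer_, 3))),
               "no masked-in")
})

test_that("the loss gradient is exactly zero at padded epochs", {
  set.seed(51)
  logits <- matrix(rnorm(8), 2, 4)
  labs <- four_class_labels(c(0L, 2L), c(TRUE, FALSE))
  lg <- insightsleep:::nll_loss_grad(logits, labs)
  expect_identical(lg$grad[2, ], rep(0, 4))
  expect_false(all(lg$grad[1, ] == 0))
  # analytic: gradient of -log softmax is p - onehot (unit weight)
  p <- softmax_with_temperature(logits[1, ])
  expect_equal(lg$grad[1, ], p - c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("backpropagation matches finite differences on a tiny network", {
  cfg <- tiny_model_config(dropout = 0)
  m <- build_model(cfg)
  set.seed(52)
  x <- runif(cfg$n_epochs * cfg$epoch_len)
  direction <- matrix(rnorm(cfg$n_epochs * 4), cfg$n_epochs)
  loss_fn <- function(model) {
    sum(insight_forward(model, x, train = TRUE)$logits * direction)
  }
  fwd <- insight_forward(m, x, train = TRUE)
  grads <- insightsleep:::insight_backward(m, fwd$cache, direction)
  eps <- 1e-6
  set.seed(53)
  for (lname in names(m$params)) {
    for (part in names(m$params[[lname]])) {
      arr <- m$params[[lname]][[part]]
      for (i in sample(length(arr), min(2, length(arr)))) {
        mp <- m; mp$params[[lname]][[part]][i] <- arr[i] + eps
        mm <- m; mm$params[[lname]][[part]][i] <- arr[i] - eps
        fd <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
        an <- grads[[lname]][[part]][i]
        ok <- abs(fd - an) < 1e-6 ||
          abs(fd - an) / max(abs(fd), abs(an)) < 1e-3
        expect_true(ok, label = paste("gradient at", lname, part, i))
      }
    }
  }
})

make_toy_data <- function(cfg, n_subjects, seed = 1) {
  lapply(seq_len(n_subjects), function(i) {
    list(input = random_epochized(cfg, n_valid = cfg$n_epochs - 2L,
                                  seed = seed + i),
         labels = random_labels(cfg$n_epochs, seed = seed + 100 + i,
                                n_valid = cfg$n_epochs - 2L))
  })
}

test_that("training reduces the loss and is seed-reproducible", {
  cfg <- tiny_model_config(dropout = 0.2)
  data <- make_toy_data(cfg, 6L, seed = 7)
  tc <- train_config(optimizer = "adam", lr = 0.003, batch_size = 2L,
                     max_epochs = 6L, seed = 9L,
                     class_weights = rep(1, 4))
  fit1 <- train_loop(build_model(cfg), data, tc)
  expect_lt(utils::tail(fit1$history$train_loss, 1),
            fit1$history$train_loss[1])
  fit2 <- train_loop(build_model(cfg), data, tc)
  expect_identical(fit1$history, fit2$history)

  # odd batching (3 subjects, batch 2) works and rmsprop descends too
  fit3 <- train_loop(build_model(cfg), data[1:3],
                     train_config(optimizer = "rmsprop", lr = 0.003,
                                  batch_size = 2L, max_epochs = 6L,
                                  seed = 2L, class_weights = rep(1, 4)))
  expect_lt(utils::tail(fit3$history$train_loss, 1),
            fit3$history$train_loss[1])
  expect_error(train_loop(build_model(cfg), list(), tc), "empty")
})

test_that("validation checkpointing returns the best-validation weights", {
  cfg <- tiny_model_config(dropout = 0)
  data <- make_toy_data(cfg, 4L, seed = 3)
  fit <- train_loop(build_model(cfg), data[1:3],
                    train_config(optimizer = "adam", lr = 0.01,
                                 batch_size = 2L, max_epochs = 4L,
                                 seed = 1L, class_weights = rep(1, 4)),
                    val_data = data[4])
  expect_false(any(is.na(fit$history$val_loss)))
  final_val <- insightsleep:::eval_loss(fit$model, data[4], rep(1, 4))
  expect_lte(final_val, min(fit$history$val_loss) + 1e-9)
})

test_that("transfer fine-tuning starts from the checkpoint and freezes nothing", {
  cfg <- tiny_model_config(dropout = 0)
  base <- build_model(cfg)
  data <- make_toy_data(cfg, 2L, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(base, path)

  # lr = 0 is the identity on the weights
  zero <- transfer_finetune(path, data,
                            train_config(optimizer = "adam", lr = 0,
                                         batch_size = 2L, max_epochs = 1L,
                                         seed = 1L,
                                         class_weights = rep(1, 4)))
  expect_identical(zero$model$params, base$params)

  # one epoch at lr > 0 changes eval logits; nothing is frozen
  tuned <- transfer_finetune(path, data,
                             train_config(optimizer = "adam", lr = 0.001,
                                          batch_size = 2L, max_epochs = 1L,
                                          seed = 1L,
                                          class_weights = rep(1, 4)))
  x <- random_epochized(cfg, seed = 77)
  expect_false(identical(insight_forward(tuned$model, x)$logits,
                         insight_forward(base, x)$logits))
  expect_identical(count_trainable_parameters(tuned$model),
                   count_trainable_parameters(base))
  for (ln in c("att_conv", "stem", "inc1_bott", "post", "tdd", "tb1_conv1",
               "head")) {
    expect_false(identical(base$params[[ln]]$w, tuned$model$params[[ln]]$w),
                 label = paste(ln, "updated"))
  }

  wrong <- tiny_model_config()
  wrong$tdd_width <- 7L
  expect_error(transfer_finetune(path, data, expected_config = wrong),
               "mismatch")
})
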
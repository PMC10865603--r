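# Independent per-epoch tally oracle used throughout this file.
tally_metrics <- function(pred, truth) {
  acc <- mean(pred == truth)
  f1 <- numeric(4)
  support <- numeric(4)
  pe <- 0
  n <- length(truth)
  for (k in 0:3) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    f1[k + 1] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    support[k + 1] <- sum(truth == k)
    pe <- pe + (sum(truth == k) / n) * (sum(pred == k) / n)
  }
  list(accuracy = acc, kappa = (acc - pe) / (1 - pe),
       weighted_f1 = sum(support / n * f1))
}

test_that("the worked 6-epoch example reproduces the formula values", {
  truth <- c(0L, 0L, 1L, 1L, 2L, 3L)
  pred <- c(0L, 1L, 1L, 1L, 2L, 3L)
  cm <- confusion_matrix(pred, truth)
  expect_equal(sum(cm), 6)
  expect_equal(cm["wake", "light"], 1L)
  expect_equal(accuracy(cm), 5 / 6)
  expect_equal(cohens_kappa(cm), 20 / 26, tolerance = 1e-12)
})

test_that("perfect and degenerate predictions hit the metric boundaries", {
  truth <- rep(0:3, each = 2)
  cm <- confusion_matrix(truth, truth)
  expect_equal(diag(cm), c(wake = 2L, light = 2L, deep = 2L, rem = 2L))
  expect_equal(accuracy(cm), 1)
  expect_equal(cohens_kappa(cm), 1)
  expect_equal(weighted_f1(cm), 1)

  # prediction independent of truth -> kappa 0 (product-form confusion)
  cm_ind <- outer(c(4, 2, 2, 2), c(5, 2, 2, 1))
  expect_lt(abs(cohens_kappa(cm_ind)), 1e-12)

  # single-cell matrix: chance agreement is 1, kappa undefined
  cm_one <- matrix(0, 4, 4, dimnames = dimnames(cm))
  cm_one[1, 1] <- 5
  expect_true(is.na(cohens_kappa(cm_one)))
  expect_error(accuracy(matrix(0, 4, 4)), "empty")
})

test_that("confusion-path metrics equal an independent tally on 100 random instances", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    truth <- sample(0:3, n, replace = TRUE, prob = runif(4) + 0.1)
    pred <- ifelse(runif(n) < 0.6, truth, sample(0:3, n, replace = TRUE))
    cm <- confusion_matrix(pred, truth)
    oracle <- tally_metrics(pred, truth)
    expect_equal(accuracy(cm), oracle$accuracy, tolerance = 1e-12)
    expect_equal(cohens_kappa(cm), oracle$kappa, tolerance = 1e-12)
    expect_equal(weighted_f1(cm), oracle$weighted_f1, tolerance = 1e-12)
  }
})

test_that("kappa agrees with caret's implementation", {
  skip_if_not_installed("caret")
  set.seed(44)
  truth <- sample(0:3, 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.7, truth, sample(0:3, 500, replace = TRUE))
  cm <- confusion_matrix(pred, truth)
  ref <- caret::confusionMatrix(factor(pred, 0:3), factor(truth, 0:3))
  expect_equal(unname(cohens_kappa(cm)), unname(ref$overall["Kappa"]),
               tolerance = 1e-10)
  expect_equal(unname(accuracy(cm)), unname(ref$overall["Accuracy"]),
               tolerance = 1e-12)
})

test_that("weighted F1 lies between the per-class extremes", {
  set.seed(45)
  for (i in 1:20) {
    truth <- sample(0:3, 100, replace = TRUE)
    pred <- ifelse(runif(100) < 0.5, truth, sample(0:3, 100, replace = TRUE))
    cm <- confusion_matrix(pred, truth)
    f1 <- per_class_f1(cm)
    f1 <- f1[!is.na(f1)]
    w <- weighted_f1(cm)
    expect_gte(w + 1e-12, min(f1))
    expect_lte(w - 1e-12, max(f1))
  }
})

test_that("masked and rejected epochs are excluded from counting", {
  truth <- c(0L, 0L, 1L, 1L, 2L, 3L)
  pred <- c(0L, 1L, 1L, 1L, 2L, 3L)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  accepted <- c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  cm <- confusion_matrix(pred, truth, mask, accepted)
  expect_equal(sum(cm), 4)  # one masked out, one rejected
  rep_ <- metric_report(pred, truth, mask, accepted)
  expect_equal(sum(rep_$confusion), 4)
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / 4)
  expect_equal(rep_$coverage, 4 / 5)
  # coverage + rejected fraction == 1 over masked-in epochs
  expect_equal(rep_$coverage + sum(mask & !accepted) / sum(mask), 1)
  expect_error(confusion_matrix(pred[1:3], truth), "lengths differ")
})

test_that("rejection breakdown reports per-cell rates against the pre-rejection state", {
  truth <- rep(0L, 10)
  pred <- rep(0L, 10)
  none <- rejection_breakdown(pred, truth,
                              accepted = rep(TRUE, 10))
  expect_equal(none["wake", "wake"], 0)
  all_rej <- rejection_breakdown(pred, truth, accepted = rep(FALSE, 10))
  expect_equal(all_rej["wake", "wake"], 1)
  expect_true(is.na(all_rej["rem", "rem"]))  # empty cell -> undefined

  # 2 of 5 (wake, wake) epochs rejected -> 0.4
  truth2 <- c(rep(0L, 5), rep(1L, 5))
  pred2 <- c(rep(0L, 5), rep(1L, 5))
  acc2 <- c(FALSE, FALSE, TRUE, TRUE, TRUE, rep(TRUE, 5))
  bd <- rejection_breakdown(pred2, truth2, accepted = acc2)
  expect_equal(bd["wake", "wake"], 0.4)
  expect_equal(bd["light", "light"], 0)
})

test_that("sleep parameters follow the TST and fraction formulas", {
  labels <- four_class_labels(rep(c(1L, 2L, 3L), times = c(100, 20, 40)))
  sp <- sleep_parameters(labels)
  expect_equal(sp$tst_minutes, 80)      # 160 sleep epochs * 0.5 min
  expect_equal(sp$fr_light, 62.5)
  expect_equal(sp$fr_deep, 12.5)
  expect_equal(sp$fr_rem, 25.0)
  expect_equal(sp$fr_light + sp$fr_deep + sp$fr_rem, 100)

  # rejecting 40 light epochs recounts everything
  accepted <- rep(TRUE, 160)
  accepted[1:40] <- FALSE
  sp2 <- sleep_parameters(labels, accepted = accepted)
  expect_equal(sp2$tst_minutes, 60)
  expect_equal(sp2$fr_light, 50.0)

  # all-wake night: zero TST, flagged, no error
  allwake <- sleep_parameters(four_class_labels(rep(0L, 50)))
  expect_equal(allwake$tst_minutes, 0)
  expect_equal(allwake$fr_light, 0)
  expect_false(allwake$defined)
})

test_that("parameter correlation matches the covariance formula", {
  est <- data.frame(tst_minutes = c(400, 350, 390, 300),
                    fr_light = c(60, 55, 62, 48),
                    fr_deep = c(15, 20, 13, 26),
                    fr_rem = c(25, 25, 25.5, 26))
  tru <- data.frame(tst_minutes = c(410, 340, 380, 310),
                    fr_light = c(58, 54, 63, 50),
                    fr_deep = c(16, 21, 12, 25),
                    fr_rem = c(26, 25, 25.2, 25))
  res <- correlate_parameters(est, tru)
  for (i in seq_len(4)) {
    a <- est[[i]]; b <- tru[[i]]
    r_direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(res$r[i], r_direct, tolerance = 1e-12)
    expect_equal(res$r_squared[i], r_direct^2, tolerance = 1e-12)
  }
  ident <- correlate_parameters(tru, tru)
  expect_equal(ident$r, rep(1, 4), tolerance = 1e-12)
  shifted <- tru
  shifted[] <- lapply(tru, function(v) v + 7)
  expect_equal(correlate_parameters(shifted, tru)$r, rep(1, 4),
               tolerance = 1e-12)
  expect_error(correlate_parameters(est[1:2, ], tru[1:2, ]), "3 subjects")
  degen <- est
  degen$fr_rem <- rep(1, 4)
  expect_error(correlate_parameters(degen, tru), "degenerate")
})
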
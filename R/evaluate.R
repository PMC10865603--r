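# Hypnogram evaluation: confusion matrices, agreement metrics, rejection
# breakdowns, and sleep parameters (total sleep time, stage fractions).

#' Confusion matrix over evaluated epochs
#'
#' Counts epochs that are masked-in AND accepted. Rows are truth, columns
#' are prediction (frozen convention), in the order wake, light, deep, rem.
#'
#' @param pred,truth integer vectors of class indices 0..3 (NA allowed where
#'   masked out).
#' @param mask logical vector of valid epochs (default all).
#' @param accepted logical vector from selective prediction (default all).
#' @return 4x4 integer matrix with dimnames truth x predicted.
#' @export
confusion_matrix <- function(pred, truth, mask = NULL, accepted = NULL) {
  n <- length(truth)
  if (length(pred) != n) stop_insight("pred and truth lengths differ")
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(accepted)) accepted <- rep(TRUE, n)
  if (length(mask) != n || length(accepted) != n) {
    stop_insight("mask/accepted must align with truth")
  }
  use <- mask & !is.na(accepted) & accepted & !is.na(pred) & !is.na(truth)
  cm <- table(factor(truth[use], levels = 0:3),
              factor(pred[use], levels = 0:3))
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(truth = FOUR_LEVELS, predicted = FOUR_LEVELS))
  cm
}

#' Accuracy, Cohen's kappa and weighted F1 from a confusion matrix
#'
#' Accuracy is trace/total. Cohen's kappa is (Pr(a) - Pr(e)) / (1 - Pr(e))
#' with Pr(a) the observed agreement and Pr(e) the chance agreement
#' sum_k row_k * col_k / total^2; it is NA when Pr(e) = 1 (a degenerate
#' single-cell matrix, where chance-corrected agreement is undefined).
#' Per-class F1 is 2TP / (2TP + FP + FN); the weighted F1 averages the
#' per-class scores weighted by class support (true counts), accounting for
#' stage imbalance.
#'
#' @param confusion 4x4 count matrix, rows truth, columns predicted.
#' @return a single numeric value (`accuracy`, `cohens_kappa`,
#'   `weighted_f1`) or a vector of 4 per-class scores (`per_class_f1`;
#'   classes with no true and no predicted epochs get NA).
#' @export
accuracy <- function(confusion) {
  tot <- sum(confusion)
  if (tot == 0) stop_insight("empty confusion matrix")
  sum(diag(confusion)) / tot
}

#' @rdname accuracy
#' @export
cohens_kappa <- function(confusion) {
  tot <- sum(confusion)
  if (tot == 0) stop_insight("empty confusion matrix")
  pa <- sum(diag(confusion)) / tot
  pe <- sum(rowSums(confusion) * colSums(confusion)) / tot^2
  if (abs(1 - pe) < .Machine$double.eps) return(NA_real_)
  (pa - pe) / (1 - pe)
}

#' @rdname accuracy
#' @export
per_class_f1 <- function(confusion) {
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom > 0, 2 * tp / denom, NA_real_)
  names(f1) <- rownames(confusion)
  f1
}

#' @rdname accuracy
#' @export
weighted_f1 <- function(confusion) {
  tot <- sum(confusion)
  if (tot == 0) stop_insight("empty confusion matrix")
  support <- rowSums(confusion)
  f1 <- per_class_f1(confusion)
  f1[is.na(f1)] <- 0  # zero-support classes contribute nothing
  sum(support / tot * f1)
}

#' Full metric report
#'
#' @param pred,truth,mask,accepted as in [confusion_matrix()].
#' @return object of class `metric_report`: accuracy, kappa, weighted F1,
#'   per-class F1, the confusion matrix and the coverage (accepted fraction
#'   of masked-in epochs).
#' @export
metric_report <- function(pred, truth, mask = NULL, accepted = NULL) {
  n <- length(truth)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(accepted)) accepted <- rep(TRUE, n)
  cm <- confusion_matrix(pred, truth, mask, accepted)
  cov <- if (sum(mask) > 0) {
    sum(mask & !is.na(accepted) & accepted) / sum(mask)
  } else NA_real_
  if (sum(cm) == 0) {
    # everything rejected or masked out: coverage is reportable, agreement
    # metrics are not
    return(structure(list(accuracy = NA_real_, kappa = NA_real_,
                          weighted_f1 = NA_real_,
                          per_class_f1 = rep(NA_real_, 4),
                          confusion = cm, coverage = cov),
                     class = "metric_report"))
  }
  structure(list(accuracy = accuracy(cm), kappa = cohens_kappa(cm),
                 weighted_f1 = weighted_f1(cm), per_class_f1 = per_class_f1(cm),
                 confusion = cm, coverage = cov),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> accuracy %.4f | kappa %.4f | weighted F1 %.4f | coverage %.3f\n",
              x$accuracy, x$kappa, x$weighted_f1, x$coverage))
  print(x$confusion)
  invisible(x)
}

#' Per-cell rejection rates
#'
#' For each (truth, pre-rejection prediction) cell, the fraction of its
#' epochs that the energy threshold rejected, relative to the state before
#' rejection. Cells with no epochs are NA.
#'
#' @param pred,truth integer class vectors (pre-rejection predictions).
#' @param mask logical valid-epoch vector.
#' @param accepted logical acceptance vector.
#' @return 4x4 numeric matrix of rejection rates in [0, 1].
#' @export
rejection_breakdown <- function(pred, truth, mask = NULL, accepted = NULL) {
  n <- length(truth)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(accepted)) accepted <- rep(TRUE, n)
  use <- mask & !is.na(pred) & !is.na(truth)
  pre <- confusion_matrix(pred, truth, mask = use)
  rejected <- use & !is.na(accepted) & !accepted
  rej <- confusion_matrix(pred, truth, mask = rejected)
  out <- ifelse(pre > 0, rej / pre, NA_real_)
  dimnames(out) <- dimnames(pre)
  out
}

#' Sleep parameters from a labeled night
#'
#' Total sleep time is 0.5 min per 30-s epoch labeled light, deep or REM
#' among masked-in (and, when supplied, accepted) epochs; stage fractions
#' are stage counts over the sleep count, in percent. All-wake nights have
#' TST 0 and fractions reported as 0 with `defined = FALSE` rather than an
#' error, so batch evaluation never aborts.
#'
#' @param labels a `four_class_labels` or integer class vector.
#' @param mask optional logical vector (defaults to the labels' own mask).
#' @param accepted optional acceptance vector from selective prediction.
#' @return object of class `sleep_parameters`: `tst_minutes`, `fr_light`,
#'   `fr_deep`, `fr_rem` (percent), `defined`.
#' @export
sleep_parameters <- function(labels, mask = NULL, accepted = NULL) {
  if (inherits(labels, "four_class_labels")) {
    y <- labels$labels
    if (is.null(mask)) mask <- labels$mask
  } else {
    y <- as.integer(labels)
    if (is.null(mask)) mask <- !is.na(y)
  }
  n <- length(y)
  if (is.null(accepted)) accepted <- rep(TRUE, n)
  use <- mask & !is.na(accepted) & accepted & !is.na(y)
  counts <- tabulate(y[use] + 1L, nbins = 4L)
  sleep_n <- sum(counts[2:4])
  tst <- 0.5 * sleep_n
  if (sleep_n > 0) {
    fr <- 100 * counts[2:4] / sleep_n
    defined <- TRUE
  } else {
    fr <- c(0, 0, 0)
    defined <- FALSE
  }
  structure(list(tst_minutes = tst, fr_light = fr[1], fr_deep = fr[2],
                 fr_rem = fr[3], defined = defined),
            class = "sleep_parameters")
}

#' @export
print.sleep_parameters <- function(x, ...) {
  cat(sprintf("<sleep_parameters> TST %.1f min | light %.1f%% | deep %.1f%% | REM %.1f%%%s\n",
              x$tst_minutes, x$fr_light, x$fr_deep, x$fr_rem,
              if (!x$defined) " (no sleep epochs)" else ""))
  invisible(x)
}

#' Correlate estimated and true sleep parameters across subjects
#'
#' Pearson r and r-squared per parameter (TST and the three stage
#' fractions) between per-subject estimates and ground truth.
#'
#' @param estimates,truths lists of [sleep_parameters()] (aligned by
#'   subject), or data.frames with columns `tst_minutes`, `fr_light`,
#'   `fr_deep`, `fr_rem`.
#' @return data.frame with columns `parameter`, `r`, `r_squared`.
#' @export
correlate_parameters <- function(estimates, truths) {
  to_df <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(p) {
      data.frame(tst_minutes = p$tst_minutes, fr_light = p$fr_light,
                 fr_deep = p$fr_deep, fr_rem = p$fr_rem)
    }))
  }
  est <- to_df(estimates)
  tru <- to_df(truths)
  if (nrow(est) != nrow(tru)) stop_insight("subject counts differ")
  if (nrow(est) < 3) stop_insight("at least 3 subjects are required")
  pars <- c("tst_minutes", "fr_light", "fr_deep", "fr_rem")
  res <- lapply(pars, function(pp) {
    a <- est[[pp]]; b <- tru[[pp]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop_insight("degenerate (zero-variance) parameter vector: ", pp)
    }
    r <- stats::cor(a, b)
    data.frame(parameter = pp, r = r, r_squared = r^2)
  })
  do.call(rbind, res)
}
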
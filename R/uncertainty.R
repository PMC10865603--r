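# Energy-score selective prediction.
#
# The energy of an epoch is the negative (temperature-scaled) log-sum-exp of
# its class logits, E(x; f) = -T * log sum_i exp(f_i / T): low for inputs
# resembling the training distribution, high for unfamiliar ones. Epochs
# whose energy exceeds a threshold tau are rejected ("don't know"); tau is
# calibrated as a quantile of the training-set energy distribution so that a
# chosen fraction of training epochs would be kept.

#' Energy score of logit vectors
#'
#' @param logits numeric vector of K class logits, or a matrix with one row
#'   per epoch.
#' @param temperature positive temperature T (default 1).
#' @return numeric energy, one value per row. Computed with an overflow-safe
#'   log-sum-exp, so extreme logits do not overflow.
#' @export
energy_score <- function(logits, temperature = 1) {
  if (temperature <= 0) stop_insight("temperature must be > 0")
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1)
  if (any(!is.finite(logits))) stop_insight("logits must be finite")
  z <- logits / temperature
  m <- apply(z, 1, max)
  lse <- m + log(rowSums(exp(z - m)))
  as.vector(-temperature * lse)
}

#' Temperature-scaled softmax
#'
#' @param logits numeric vector (or matrix, one row per epoch) of logits.
#' @param temperature positive temperature; as T grows the distribution
#'   approaches uniform.
#' @return probabilities of the same shape, (rows) summing to one.
#' @export
softmax_with_temperature <- function(logits, temperature = 1) {
  if (temperature <= 0) stop_insight("temperature must be > 0")
  vec <- !is.matrix(logits)
  if (vec) logits <- matrix(logits, nrow = 1)
  p <- t(softmax_cols(t(logits / temperature)))
  if (vec) as.vector(p) else p
}

#' Calibrate the energy rejection threshold
#'
#' Returns the threshold tau at which a fraction `keep_fraction` of the
#' supplied training energies satisfies `energy <= tau`. The lower empirical
#' quantile (order statistic at `ceiling(keep_fraction * n)`) is used, which
#' is reproducible across numeric stacks.
#'
#' @param train_energies energies of training-set epochs (pooled across
#'   subjects).
#' @param keep_fraction fraction in (0, 1] of training epochs to keep; the
#'   published operating points are 0.80, 0.85, 0.90 and 0.95.
#' @return numeric threshold tau.
#' @export
calibrate_threshold <- function(train_energies, keep_fraction) {
  if (length(train_energies) == 0) stop_insight("no training energies given")
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop_insight("keep_fraction must lie in (0, 1]")
  }
  sort(train_energies)[ceiling(keep_fraction * length(train_energies))]
}

#' Selective prediction under an energy threshold
#'
#' For every masked-in epoch of a logits grid: the predicted class is the
#' probability argmax, the energy is computed from the epoch's logits, and
#' the epoch is accepted iff its energy is at or below tau. Rejected epochs
#' keep their prediction for audit but are excluded from metrics downstream.
#' Masked-out (padded) epochs are neither accepted nor rejected.
#'
#' @param logits matrix `n_epochs x n_classes` of pre-softmax scores.
#' @param mask logical vector of valid epochs (default all valid).
#' @param tau energy threshold.
#' @param temperature positive temperature for energy and probabilities.
#' @return a `selective_result` data.frame with one row per epoch: columns
#'   `epoch`, `predicted` (integer class 0..K-1), `energy`, `accepted`
#'   (NA for masked-out epochs), plus attributes `tau` and `temperature`.
#' @export
selective_predict <- function(logits, mask = NULL, tau = Inf,
                              temperature = 1) {
  stopifnot(is.matrix(logits))
  n <- nrow(logits)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  probs <- softmax_with_temperature(logits, temperature)
  pred <- max.col(probs, ties.method = "first") - 1L
  energy <- energy_score(logits, temperature)
  accepted <- ifelse(mask, energy <= tau, NA)
  res <- data.frame(epoch = seq_len(n), predicted = pred,
                    energy = energy, accepted = accepted)
  res$predicted[!mask] <- NA_integer_
  res$energy[!mask] <- NA_real_
  attr(res, "tau") <- tau
  attr(res, "temperature") <- temperature
  class(res) <- c("selective_result", "data.frame")
  res
}

#' Pool training energies from a fitted model over a dataset
#'
#' Runs the model in eval mode over a list of epochized inputs and collects
#' the energy of every masked-in epoch, the calibration pool for
#' [calibrate_threshold()].
#'
#' @param model a `sleep_model`.
#' @param inputs list of [epochized_input] objects.
#' @param temperature energy temperature.
#' @return numeric vector of energies.
#' @export
pool_training_energies <- function(model, inputs, temperature = 1) {
  unlist(lapply(inputs, function(ep) {
    out <- insight_forward(model, ep)
    energy_score(out$logits, temperature)[epoch_mask(ep)]
  }), use.names = FALSE)
}
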
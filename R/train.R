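# Class-weighted, mask-aware training: NLL loss over masked-in epochs,
# RMSprop / Adam optimizers, subject-level batches (one example = one full
# standardized night) and transfer fine-tuning with nothing frozen.

#' Masked, class-weighted negative log likelihood
#'
#' loss = sum over masked-in epochs of weight[y] * (-log p[y]), divided by
#' the summed weights of the contributing epochs (a weighted mean, so the
#' loss scale is comparable across class mixes). Padded or unscored epochs
#' contribute nothing.
#'
#' @param log_probs matrix `n_epochs x 4` of log class probabilities.
#' @param labels a [four_class_labels()] aligned with the rows.
#' @param weights 4 positive class weights (default all 1).
#' @return scalar loss.
#' @export
masked_weighted_nll <- function(log_probs, labels, weights = rep(1, 4)) {
  stopifnot(is.matrix(log_probs), inherits(labels, "four_class_labels"))
  if (nrow(log_probs) != length(labels$labels)) {
    stop_insight("log_probs rows must match label length")
  }
  use <- which(labels$mask)
  if (length(use) == 0) stop_insight("no masked-in epochs")
  y <- labels$labels[use]
  w <- weights[y + 1L]
  nll <- -log_probs[cbind(use, y + 1L)]
  sum(w * nll) / sum(w)
}

# Loss and its gradient at the logits, in one pass.
nll_loss_grad <- function(logits, labels, weights = rep(1, 4)) {
  n <- nrow(logits)
  probs <- t(softmax_cols(t(logits)))
  use <- which(labels$mask)
  y <- labels$labels[use]
  w <- weights[y + 1L]
  z <- sum(w)
  p_true <- probs[cbind(use, y + 1L)]
  loss <- sum(w * (-log(pmax(p_true, 1e-12)))) / z
  grad <- matrix(0, n, ncol(logits))
  onehot <- matrix(0, length(use), ncol(logits))
  onehot[cbind(seq_along(use), y + 1L)] <- 1
  grad[use, ] <- (w / z) * (probs[use, , drop = FALSE] - onehot)
  list(loss = loss, grad = grad)
}

#' Training configuration
#'
#' @param optimizer `"rmsprop"` or `"adam"` (both with the published
#'   learning rate 0.001 by default).
#' @param lr learning rate.
#' @param batch_size recordings per batch (default 2).
#' @param max_epochs training epochs (default 100; the only stopping rule).
#' @param seed seed controlling shuffling and dropout.
#' @param class_weights optional 4 weights; computed from the training
#'   labels by [class_weights()] when NULL.
#' @param transfer_from optional checkpoint path to initialize from.
#' @return object of class `train_config`.
#' @export
train_config <- function(optimizer = c("rmsprop", "adam"), lr = 0.001,
                         batch_size = 2L, max_epochs = 100L, seed = 1L,
                         class_weights = NULL, transfer_from = NULL) {
  optimizer <- match.arg(optimizer)
  if (lr < 0) stop_insight("lr must be >= 0")
  if (batch_size < 1) stop_insight("batch_size must be >= 1")
  structure(list(optimizer = optimizer, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 class_weights = class_weights, transfer_from = transfer_from),
            class = "train_config")
}

opt_init <- function(params) {
  rapply(params, function(a) {
    if (is.null(dim(a))) numeric(length(a)) else array(0, dim = dim(a))
  }, how = "replace")
}

opt_step <- function(kind, params, grads, state, lr, t) {
  eps <- 1e-8
  for (lname in names(grads)) {
    for (part in names(grads[[lname]])) {
      g <- grads[[lname]][[part]]
      if (kind == "rmsprop") {
        state$sq[[lname]][[part]] <-
          0.99 * state$sq[[lname]][[part]] + 0.01 * g^2
        params[[lname]][[part]] <- params[[lname]][[part]] -
          lr * g / (sqrt(state$sq[[lname]][[part]]) + eps)
      } else {
        state$m[[lname]][[part]] <-
          0.9 * state$m[[lname]][[part]] + 0.1 * g
        state$v[[lname]][[part]] <-
          0.999 * state$v[[lname]][[part]] + 0.001 * g^2
        mhat <- state$m[[lname]][[part]] / (1 - 0.9^t)
        vhat <- state$v[[lname]][[part]] / (1 - 0.999^t)
        params[[lname]][[part]] <- params[[lname]][[part]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(params = params, state = state)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (lname in names(b)) {
    for (part in names(b[[lname]])) {
      a[[lname]][[part]] <- a[[lname]][[part]] + b[[lname]][[part]]
    }
  }
  a
}

scale_grads <- function(a, s) {
  rapply(a, function(g) g * s, how = "replace")
}

eval_loss <- function(model, data, weights) {
  mean(vapply(data, function(d) {
    out <- insight_forward(model, d$input)
    masked_weighted_nll(log(pmax(out$probs, 1e-12)), d$labels, weights)
  }, numeric(1)))
}

#' Train the network
#'
#' Mini-batch optimization over a list of recordings. One training example
#' is one full standardized night; gradients are averaged within each
#' batch. A fixed seed makes the loss trajectory reproducible on a given
#' platform. When validation data is supplied, the returned model carries
#' the weights with the best validation loss.
#'
#' @param model a `sleep_model` (freshly built or loaded).
#' @param data list of `list(input = epochized_input, labels =
#'   four_class_labels)`, labels aligned to the model grid.
#' @param config a [train_config()].
#' @param val_data optional validation list of the same shape.
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained), `history` (data.frame: epoch,
#'   train_loss, val_loss), `class_weights`.
#' @export
train_loop <- function(model, data, config = train_config(),
                       val_data = NULL, verbose = FALSE) {
  if (length(data) == 0) stop_insight("empty training set")
  weights <- config$class_weights %||%
    class_weights(lapply(data, `[[`, "labels"))
  state <- list(sq = opt_init(model$params), m = opt_init(model$params),
                v = opt_init(model$params))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = model$params, buffers = model$buffers)
  t_step <- 0L
  with_seed_local(config$seed, {
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(length(data))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_losses <- c()
      for (bt in batches) {
        grads <- NULL
        bloss <- 0
        for (i in bt) {
          out <- insight_forward(model, data[[i]]$input, train = TRUE)
          model$buffers <- out$buffers
          lg <- nll_loss_grad(out$logits, data[[i]]$labels, weights)
          g <- insight_backward(model, out$cache, lg$grad)
          grads <- add_grads(grads, g)
          bloss <- bloss + lg$loss
        }
        grads <- scale_grads(grads, 1 / length(bt))
        t_step <- t_step + 1L
        upd <- opt_step(config$optimizer, model$params, grads, state,
                        config$lr, t_step)
        model$params <- upd$params
        state <- upd$state
        ep_losses <- c(ep_losses, bloss / length(bt))
      }
      vl <- if (!is.null(val_data)) eval_loss(model, val_data, weights)
            else NA_real_
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = mean(ep_losses),
                                           val_loss = vl))
      if (!is.null(val_data) && vl < best$loss) {
        best <- list(loss = vl, params = model$params,
                     buffers = model$buffers)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %s", ep,
                        mean(ep_losses),
                        if (is.na(vl)) "-" else sprintf("%.4f", vl)))
      }
    }
  })
  if (!is.null(val_data) && is.finite(best$loss)) {
    model$params <- best$params
    model$buffers <- best$buffers
  }
  list(model = model, history = history, class_weights = weights)
}

#' Transfer fine-tuning
#'
#' Initializes every weight from a pre-trained checkpoint (architecture
#' must match) and trains all parameters - nothing is frozen.
#'
#' @param base_checkpoint path to a checkpoint or a `sleep_model`.
#' @param data,config,val_data,verbose as in [train_loop()].
#' @param expected_config optional [model_config()] the checkpoint must
#'   match architecturally (all fields except the initialization seed).
#' @return as [train_loop()].
#' @export
transfer_finetune <- function(base_checkpoint, data,
                              config = train_config(optimizer = "adam"),
                              val_data = NULL, verbose = FALSE,
                              expected_config = NULL) {
  base <- if (inherits(base_checkpoint, "sleep_model")) base_checkpoint
          else load_checkpoint(base_checkpoint)
  if (!is.null(expected_config)) {
    arch <- function(cfg) unclass(cfg)[setdiff(names(cfg), "init_seed")]
    if (!isTRUE(all.equal(arch(base$config), arch(expected_config)))) {
      stop_insight("checkpoint configuration mismatch")
    }
  }
  train_loop(base, data, config, val_data, verbose)
}
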
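# Forward pass. Signals are channels x time matrices throughout; the cache
# produced under `train = TRUE` carries every intermediate the backward pass
# needs (see backward.R, which mirrors this structure layer for layer).

conv1x1_fwd <- function(x, layer) {
  out <- matrix(layer$w[, , 1], nrow = dim(layer$w)[1]) %*% x
  if (!is.null(layer$b)) out <- out + layer$b
  out
}

same_pad <- function(k) {
  pl <- (k - 1L) %/% 2L
  c(pl, k - 1L - pl)
}

bn_fwd <- function(x, layer, buffer, train, eps = 1e-5, momentum = 0.1) {
  if (train) {
    m <- rowMeans(x)
    v <- rowMeans((x - m)^2)
    inv_std <- 1 / sqrt(v + eps)
    xhat <- (x - m) * inv_std
    out <- layer$gamma * xhat + layer$beta
    buffer$mean <- (1 - momentum) * buffer$mean + momentum * m
    buffer$var <- (1 - momentum) * buffer$var + momentum * v
    list(out = out, cache = list(xhat = xhat, inv_std = inv_std),
         buffer = buffer)
  } else {
    inv_std <- 1 / sqrt(buffer$var + eps)
    out <- layer$gamma * ((x - buffer$mean) * inv_std) + layer$beta
    list(out = out, cache = NULL, buffer = buffer)
  }
}

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1L, 1 - p), nrow(x)) / (1 - p)
  list(out = x * mask, mask = mask)
}

flatten_input <- function(x, config) {
  if (inherits(x, "epochized_input")) x <- x$values
  if (is.matrix(x)) {
    if (nrow(x) != config$n_epochs || ncol(x) != config$epoch_len) {
      stop_insight("input grid is ", nrow(x), " x ", ncol(x),
                   " but the model expects ", config$n_epochs, " x ",
                   config$epoch_len)
    }
    x <- as.vector(t(x))
  }
  if (length(x) != config$n_epochs * config$epoch_len) {
    stop_insight("input length ", length(x), " != n_epochs * epoch_len")
  }
  as.numeric(x)
}

attention_component <- function(model, xflat, train) {
  cfg <- model$config
  p <- model$params
  K <- cfg$attention_kernel
  ca <- cfg$attention_channels
  v1 <- as.vector(p$att_proj$w[1, , 1])
  use_fft <- att_use_fft(K, length(xflat), ca)
  if (use_fft) {
    af <- att_fft_forward(xflat, p$att_conv$w, p$att_conv$b, v1,
                          p$att_proj$b, keep_A = train)
    s_pre <- af$s_pre
    A <- af$A
  } else {
    A <- cpp_conv1d_forward(matrix(xflat, 1), p$att_conv$w, p$att_conv$b,
                            1L, 1L, K - 1L, 0L)
    s_pre <- as.vector(v1 %*% A) + p$att_proj$b
  }
  attn <- sigmoid(s_pre)
  list(xw = xflat * attn, attn = attn,
       cache = if (train) list(x = xflat, A = A, attn = attn,
                               use_fft = use_fft))
}

inception_component <- function(model, xw, train, buffers,
                                keep_prepool = FALSE) {
  cfg <- model$config
  p <- model$params
  cache <- if (train) list()
  pad <- c(0L, 0L)
  if (cfg$stem_kernel > cfg$stem_stride) {
    tot <- cfg$stem_kernel - cfg$stem_stride
    pad <- c(tot %/% 2L, tot - tot %/% 2L)
  }
  stem_pre <- cpp_conv1d_forward(matrix(xw, 1), p$stem$w, p$stem$b,
                                 cfg$stem_stride, 1L, pad[1], pad[2])
  h <- relu(stem_pre)
  if (train) cache$stem <- list(xin = xw, pre = stem_pre, pad = pad)

  for (b in seq_along(cfg$inception_in)) {
    nm <- function(part) paste0("inc", b, "_", part)
    x_in <- h
    bott <- conv1x1_fwd(x_in, p[[nm("bott")]])
    branches <- vector("list", 4L)
    for (j in 1:3) {
      k <- cfg$inception_kernels[j]
      sp <- same_pad(k)
      branches[[j]] <- cpp_conv1d_forward(bott, p[[nm(paste0("conv", j))]]$w,
                                          p[[nm(paste0("conv", j))]]$b,
                                          1L, 1L, sp[1], sp[2])
    }
    mp <- cpp_maxpool1d_forward(x_in, 3L, 1L, 1L)
    branches[[4]] <- conv1x1_fwd(mp$out, p[[nm("pool")]])
    cat_out <- do.call(rbind, branches)
    bn <- bn_fwd(cat_out, p[[nm("bn")]], buffers[[nm("bn")]], train)
    buffers[[nm("bn")]] <- bn$buffer
    res_pre <- conv1x1_fwd(x_in, p[[nm("res")]])
    rbn <- bn_fwd(res_pre, p[[nm("resbn")]], buffers[[nm("resbn")]], train)
    buffers[[nm("resbn")]] <- rbn$buffer
    s <- bn$out + rbn$out
    h <- relu(s)
    if (train) {
      cache[[nm("blk")]] <- list(x_in = x_in, bott = bott,
                                 mp_out = mp$out, mp_argmax = mp$argmax,
                                 bn_cache = bn$cache, rbn_cache = rbn$cache,
                                 s = s, nf = cfg$inception_filters[b])
    }
  }

  L_feat <- ncol(h)
  ap <- cpp_adaptive_avgpool_forward(h, cfg$n_epochs)
  post <- conv1x1_fwd(ap, p$post)
  if (train) cache$pool <- list(L_feat = L_feat, ap = ap, post = post)
  out <- list(feats = post, cache = cache, buffers = buffers)
  if (keep_prepool) out$prepool <- h
  out
}

tcn_component <- function(model, t_in, train) {
  cfg <- model$config
  p <- model$params
  cache <- if (train) list()
  kt <- cfg$tcn_kernel
  zb <- numeric(cfg$tcn_channels)
  for (j in seq_len(cfg$tcn_blocks)) {
    nm <- function(part) paste0("tb", j, "_", part)
    d <- cfg$tcn_dilations[j]
    plt <- (kt - 1L) * d
    z1 <- cpp_conv1d_forward(t_in, p[[nm("conv1")]]$w, zb, 1L, d, plt, 0L)
    r1 <- relu(z1)
    d1 <- dropout_fwd(r1, cfg$tcn_dropout, train)
    z2 <- cpp_conv1d_forward(d1$out, p[[nm("conv2")]]$w, zb, 1L, d, plt, 0L)
    r2 <- relu(z2)
    d2 <- dropout_fwd(r2, cfg$tcn_dropout, train)
    skip <- if (!is.null(p[[nm("down")]])) conv1x1_fwd(t_in, p[[nm("down")]])
            else t_in
    s <- skip + d2$out
    if (train) {
      cache[[nm("blk")]] <- list(t_in = t_in, z1 = z1, mask1 = d1$mask,
                                 d1 = d1$out, z2 = z2, mask2 = d2$mask,
                                 s = s)
    }
    t_in <- relu(s)
  }
  list(out = t_in, cache = cache)
}

#' Run the network forward
#'
#' Maps a standardized input grid (`n_epochs` x `epoch_len`, flattened in
#' time order) to per-epoch class logits and probabilities. In `train` mode
#' dropout is active, batch-norm uses per-recording statistics (updating the
#' running buffers) and a cache of intermediates is returned for
#' backpropagation; in eval mode the pass is deterministic.
#'
#' Padded epochs still produce logits; masking them out is the caller's
#' responsibility (loss and metrics, not the network, consume the mask).
#'
#' @param model a `sleep_model`.
#' @param x an [epochized_input], an `n_epochs x epoch_len` matrix, or a
#'   flat numeric vector.
#' @param train logical; enables dropout/batch statistics and caching.
#' @return a list with `logits` (n_epochs x n_classes), `probs` (same shape,
#'   rows summing to 1), `attention` (per-sample gate values in (0,1)),
#'   `buffers` (possibly updated running statistics) and, when `train`,
#'   `cache`.
#' @export
insight_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  xflat <- flatten_input(x, cfg)
  att <- attention_component(model, xflat, train)
  inc <- inception_component(model, att$xw, train, model$buffers)
  tdd <- conv1x1_fwd(inc$feats, model$params$tdd)
  tcn <- tcn_component(model, tdd, train)
  logits <- conv1x1_fwd(tcn$out, model$params$head)
  probs <- softmax_cols(logits)
  out <- list(logits = t(logits), probs = t(probs),
              attention = att$attn, buffers = inc$buffers)
  if (train) {
    cache <- inc$cache
    cache$att <- att$cache
    cache$head <- list(t_last = tcn$out)
    out$cache <- c(cache, tcn$cache)
  }
  out
}

#' Local attention module, run in isolation
#'
#' Applies the causal attention gate to a flat input sequence: a causal
#' convolution spanning seven epochs (the preceding three minutes plus the
#' current position), a 1x1 projection to a single score channel and a
#' sigmoid. The gate at sample t depends only on samples at or before t.
#'
#' @param model a `sleep_model`.
#' @param x input of length `n_epochs * epoch_len` (or epoch grid).
#' @return list with `weighted` (gated signal) and `attention`
#'   (per-sample scores in (0,1)).
#' @export
local_attention_forward <- function(model, x) {
  xflat <- flatten_input(x, model$config)
  att <- attention_component(model, xflat, train = FALSE)
  list(weighted = att$xw, attention = att$attn)
}

#' InceptionTime module, run in isolation
#'
#' Stem convolution, the InceptionTime block stack, adaptive average pooling
#' to the epoch grid and the closing 1x1 convolution, in eval mode.
#'
#' @param model a `sleep_model`.
#' @param weighted attention-weighted input sequence (flat vector).
#' @return feature matrix, `post_channels x n_epochs`.
#' @export
inception_module_forward <- function(model, weighted) {
  stopifnot(length(weighted) == model$config$n_epochs * model$config$epoch_len)
  inception_component(model, as.numeric(weighted), train = FALSE,
                      model$buffers)$feats
}

#' Temporal convolutional stack, run in isolation
#'
#' The dilated causal temporal blocks, in eval mode. Output at epoch e
#' depends only on input epochs at or before e; the stack's receptive field
#' is `1 + (k - 1) * 2 * sum(dilations)` epochs.
#'
#' @param model a `sleep_model`.
#' @param feats per-epoch feature matrix, `tdd_width x n_epochs`.
#' @return feature matrix, `tcn_channels x n_epochs`.
#' @export
temporal_stack_forward <- function(model, feats) {
  stopifnot(nrow(feats) == model$config$tdd_width,
            ncol(feats) == model$config$n_epochs)
  tcn_component(model, feats, train = FALSE)$out
}

#' Extract the attention map for an input
#'
#' Runs the attention module in eval mode and returns per-sample scores, the
#' per-epoch aggregate (mean of the 1024 per-sample scores in each epoch)
#' and a min-max normalized per-sample view over the valid (unpadded) part
#' of the recording, for plotting.
#'
#' @param model a `sleep_model`.
#' @param x an [epochized_input] (its mask restricts the normalized view) or
#'   flat input vector.
#' @return object of class `attention_map`: list with `per_sample`,
#'   `per_epoch`, `normalized`, `n_valid_epochs`.
#' @export
extract_attention <- function(model, x) {
  cfg <- model$config
  n_valid <- if (inherits(x, "epochized_input")) x$n_valid_epochs
             else cfg$n_epochs
  xflat <- flatten_input(x, cfg)
  attn <- attention_component(model, xflat, train = FALSE)$attn
  per_epoch <- colMeans(matrix(attn, nrow = cfg$epoch_len))
  valid <- seq_len(n_valid * cfg$epoch_len)
  rng <- range(attn[valid])
  normalized <- attn
  normalized[valid] <- if (diff(rng) > 0) (attn[valid] - rng[1]) / diff(rng)
                       else 0
  structure(list(per_sample = attn, per_epoch = per_epoch,
                 normalized = normalized, n_valid_epochs = n_valid),
            class = "attention_map")
}
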
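# Backpropagation. Mirrors forward.R layer for layer, consuming the cache
# written under train = TRUE. Gradient correctness is pinned by a central
# finite-difference test in the suite.

conv1x1_bwd <- function(x, layer, grad_out) {
  w1 <- matrix(layer$w[, , 1], nrow = dim(layer$w)[1])
  g <- list(w = array(grad_out %*% t(x), dim = dim(layer$w)))
  if (!is.null(layer$b)) g$b <- rowSums(grad_out)
  list(grads = g, grad_x = t(w1) %*% grad_out)
}

bn_bwd <- function(grad_out, layer, cache) {
  xhat <- cache$xhat
  n <- ncol(xhat)
  g_gamma <- rowSums(grad_out * xhat)
  g_beta <- rowSums(grad_out)
  dxhat <- grad_out * layer$gamma
  dx <- (cache$inv_std / n) *
    (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(grads = list(gamma = g_gamma, beta = g_beta), grad_x = dx)
}

#' Backward pass of the network
#'
#' Computes the gradient of a scalar loss with respect to every trainable
#' parameter, given the cache from a `train = TRUE` forward pass and the
#' loss gradient at the logits.
#'
#' @param model a `sleep_model`.
#' @param cache the cache element of [insight_forward()] output.
#' @param grad_logits gradient at the logits, `n_epochs x n_classes` (the
#'   orientation [insight_forward()] returns logits in).
#' @return named list of gradient arrays mirroring `model$params`.
#' @keywords internal
insight_backward <- function(model, cache, grad_logits) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  g <- t(grad_logits)  # classes x epochs, internal orientation

  hb <- conv1x1_bwd(cache$head$t_last, p$head, g)
  grads$head <- hb$grads
  g_h <- hb$grad_x

  kt <- cfg$tcn_kernel
  zero_b <- numeric(cfg$tcn_channels)
  for (j in rev(seq_len(cfg$tcn_blocks))) {
    nm <- function(part) paste0("tb", j, "_", part)
    ch <- cache[[nm("blk")]]
    d <- cfg$tcn_dilations[j]
    plt <- (kt - 1L) * d
    gs <- g_h * (ch$s > 0)
    g_d2 <- gs
    g_r2 <- if (is.null(ch$mask2)) g_d2 else g_d2 * ch$mask2
    g_z2 <- g_r2 * (ch$z2 > 0)
    bw2 <- cpp_conv1d_backward(ch$d1, p[[nm("conv2")]]$w, g_z2, 1L, d, plt, 0L)
    grads[[nm("conv2")]] <- list(w = bw2$grad_w)
    g_d1 <- bw2$grad_x
    g_r1 <- if (is.null(ch$mask1)) g_d1 else g_d1 * ch$mask1
    g_z1 <- g_r1 * (ch$z1 > 0)
    bw1 <- cpp_conv1d_backward(ch$t_in, p[[nm("conv1")]]$w, g_z1, 1L, d, plt, 0L)
    grads[[nm("conv1")]] <- list(w = bw1$grad_w)
    g_tin <- bw1$grad_x
    if (!is.null(p[[nm("down")]])) {
      db <- conv1x1_bwd(ch$t_in, p[[nm("down")]], gs)
      grads[[nm("down")]] <- db$grads
      g_tin <- g_tin + db$grad_x
    } else {
      g_tin <- g_tin + gs
    }
    g_h <- g_tin
  }

  tb <- conv1x1_bwd(cache$pool$post, p$tdd, g_h)
  grads$tdd <- tb$grads
  pb <- conv1x1_bwd(cache$pool$ap, p$post, tb$grad_x)
  grads$post <- pb$grads
  g_feat <- cpp_adaptive_avgpool_backward(pb$grad_x, cache$pool$L_feat)

  nb <- length(cfg$inception_in)
  for (b in rev(seq_len(nb))) {
    nm <- function(part) paste0("inc", b, "_", part)
    ch <- cache[[nm("blk")]]
    gs <- g_feat * (ch$s > 0)
    bnb <- bn_bwd(gs, p[[nm("bn")]], ch$bn_cache)
    grads[[nm("bn")]] <- bnb$grads
    g_cat <- bnb$grad_x
    rbnb <- bn_bwd(gs, p[[nm("resbn")]], ch$rbn_cache)
    grads[[nm("resbn")]] <- rbnb$grads
    rb <- conv1x1_bwd(ch$x_in, p[[nm("res")]], rbnb$grad_x)
    grads[[nm("res")]] <- rb$grads
    g_xin <- rb$grad_x

    nf <- ch$nf
    g_bott <- NULL
    for (j in 1:3) {
      rows <- ((j - 1L) * nf + 1L):(j * nf)
      k <- cfg$inception_kernels[j]
      sp <- same_pad(k)
      bwj <- cpp_conv1d_backward(ch$bott, p[[nm(paste0("conv", j))]]$w,
                                 g_cat[rows, , drop = FALSE],
                                 1L, 1L, sp[1], sp[2])
      grads[[nm(paste0("conv", j))]] <- list(w = bwj$grad_w, b = as.vector(bwj$grad_b))
      g_bott <- if (is.null(g_bott)) bwj$grad_x else g_bott + bwj$grad_x
    }
    rows4 <- (3L * nf + 1L):(4L * nf)
    pb4 <- conv1x1_bwd(ch$mp_out, p[[nm("pool")]],
                       g_cat[rows4, , drop = FALSE])
    grads[[nm("pool")]] <- pb4$grads
    g_xin <- g_xin + cpp_maxpool1d_backward(pb4$grad_x, ch$mp_argmax,
                                            ncol(ch$x_in))
    bb <- conv1x1_bwd(ch$x_in, p[[nm("bott")]], g_bott)
    grads[[nm("bott")]] <- bb$grads
    g_xin <- g_xin + bb$grad_x
    g_feat <- g_xin
  }

  g_stem_pre <- g_feat * (cache$stem$pre > 0)
  sb <- cpp_conv1d_backward(matrix(cache$stem$xin, 1), p$stem$w, g_stem_pre,
                            cfg$stem_stride, 1L,
                            cache$stem$pad[1], cache$stem$pad[2])
  grads$stem <- list(w = sb$grad_w, b = as.vector(sb$grad_b))
  g_xw <- as.vector(sb$grad_x)

  att <- cache$att
  attn <- att$attn
  g_attn <- g_xw * att$x
  grad_s <- g_attn * attn * (1 - attn)
  v1 <- as.vector(p$att_proj$w[1, , 1])
  if (att$use_fft) {
    ab <- att_fft_backward(att$x, p$att_conv$w, v1, att$A, grad_s)
    grads$att_conv <- ab$att_conv
    grads$att_proj <- ab$att_proj
  } else {
    gA <- outer(v1, grad_s)
    cb <- cpp_conv1d_backward(matrix(att$x, 1), p$att_conv$w, gA, 1L, 1L,
                              cfg$attention_kernel - 1L, 0L)
    grads$att_conv <- list(w = cb$grad_w, b = as.vector(cb$grad_b))
    grads$att_proj <- list(w = array(as.vector(att$A %*% grad_s),
                                     dim = c(1, cfg$attention_channels, 1)),
                           b = sum(grad_s))
  }
  grads
}
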
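# Network construction, parameter bookkeeping and checkpoints.

with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

conv_init <- function(c_out, c_in, k, bias = TRUE) {
  bound <- 1 / sqrt(c_in * k)
  out <- list(w = array(stats::runif(c_out * c_in * k, -bound, bound),
                        dim = c(c_out, c_in, k)))
  if (bias) out$b <- stats::runif(c_out, -bound, bound)
  out
}

#' Build the sleep-staging network
#'
#' Allocates and initializes every weight tensor of the architecture
#' described by a [model_config()]: local attention (causal convolution +
#' 1x1 projection + sigmoid gate), stem convolution, InceptionTime blocks
#' (bottleneck, three branch convolutions, max-pool projection, batch
#' normalization, 1x1 residual shortcut with its own normalization),
#' adaptive pooling, 1x1 post convolution, time-distributed dense layer,
#' dilated causal temporal blocks and the 1x1 class head. Initialization is
#' fan-in-scaled uniform, seeded by `config$init_seed`.
#'
#' @param config a [model_config()].
#' @return an object of class `sleep_model` with elements `config`, `params`
#'   (named list of trainable arrays) and `buffers` (batch-norm running
#'   statistics).
#' @export
build_model <- function(config = model_config()) {
  validate_model_config(config)
  params <- list()
  buffers <- list()
  with_seed_local(config$init_seed, {
    ca <- config$attention_channels
    params$att_conv <- conv_init(ca, 1L, config$attention_kernel)
    params$att_proj <- conv_init(1L, ca, 1L)
    params$stem <- conv_init(config$stem_channels, 1L, config$stem_kernel)
    nb <- length(config$inception_in)
    for (b in seq_len(nb)) {
      ic <- config$inception_in[b]
      f <- config$inception_filters[b]
      bo <- config$inception_bottleneck[b]
      oc <- 4L * f
      nm <- function(part) paste0("inc", b, "_", part)
      params[[nm("bott")]] <- conv_init(bo, ic, 1L)
      for (j in 1:3) {
        params[[nm(paste0("conv", j))]] <-
          conv_init(f, bo, config$inception_kernels[j])
      }
      params[[nm("pool")]] <- conv_init(f, ic, 1L)
      params[[nm("bn")]] <- list(gamma = rep(1, oc), beta = rep(0, oc))
      params[[nm("res")]] <- conv_init(oc, ic, 1L)
      params[[nm("resbn")]] <- list(gamma = rep(1, oc), beta = rep(0, oc))
      buffers[[nm("bn")]] <- list(mean = rep(0, oc), var = rep(1, oc))
      buffers[[nm("resbn")]] <- list(mean = rep(0, oc), var = rep(1, oc))
    }
    oc_last <- 4L * config$inception_filters[nb]
    params$post <- conv_init(config$post_channels, oc_last, 1L)
    params$tdd <- conv_init(config$tdd_width, config$post_channels, 1L)
    in_ch <- config$tdd_width
    for (j in seq_len(config$tcn_blocks)) {
      nm <- function(part) paste0("tb", j, "_", part)
      params[[nm("conv1")]] <-
        conv_init(config$tcn_channels, in_ch, config$tcn_kernel, bias = FALSE)
      params[[nm("conv2")]] <-
        conv_init(config$tcn_channels, config$tcn_channels, config$tcn_kernel,
                  bias = FALSE)
      if (in_ch != config$tcn_channels) {
        params[[nm("down")]] <- conv_init(config$tcn_channels, in_ch, 1L)
      }
      in_ch <- config$tcn_channels
    }
    params$head <- conv_init(config$n_classes, config$tcn_channels, 1L)
  })
  structure(list(config = config, params = params, buffers = buffers),
            class = "sleep_model")
}

#' Count trainable parameters
#'
#' Sums the element counts of every trainable weight array (convolution
#' kernels, biases, batch-norm scale/shift). Running statistics are buffers,
#' not parameters. The count is a pure function of the configuration; the
#' full default configuration has 1,922,397 parameters.
#'
#' @param model a `sleep_model`.
#' @return integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "sleep_model"))
  sum(vapply(model$params,
             function(layer) sum(vapply(layer, length, integer(1))),
             numeric(1)))
}

#' @export
print.sleep_model <- function(x, ...) {
  cat("<sleep_model>\n")
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_parameters(x), big.mark = ",")))
  cat(sprintf("  input grid: %d epochs x %d samples -> logits (%d, %d)\n",
              x$config$n_epochs, x$config$epoch_len,
              x$config$n_epochs, x$config$n_classes))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the full weight set, the running batch-norm buffers and
#' the configuration (also embedded as JSON for language-neutral
#' inspection). A reloaded checkpoint reproduces eval-mode logits exactly.
#'
#' @param model a `sleep_model`.
#' @param path file path.
#' @return `load_checkpoint` returns a `sleep_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sleep_model"))
  saveRDS(list(
    config = unclass(model$config),
    config_json = jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE),
    params = model$params,
    buffers = model$buffers
  ), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_insight("checkpoint not found: ", path)
  raw <- readRDS(path)
  cfg <- raw$config
  class(cfg) <- "model_config"
  structure(list(config = cfg, params = raw$params, buffers = raw$buffers),
            class = "sleep_model")
}
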
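#' Network configuration
#'
#' Assembles and validates the hyperparameter set of the sleep-staging
#' network. The defaults are the full-size published configuration: a causal
#' local-attention module whose kernel spans 7 epochs (7 x 1024 = 7168
#' samples, the "3-minute rule" context window), a 32-channel stem
#' convolution (kernel 40, stride 20), six InceptionTime blocks with input
#' channels 32, 32, 64, 64, 128, 256, per-branch filters 8, 16, 16, 32, 64,
#' 128 and bottlenecks 8, 16, 16, 16, 32, 32 (branch kernels 5, 11, 23),
#' adaptive average pooling to the epoch grid followed by a 1x1 convolution
#' to 256 channels, a time-distributed dense layer of width 64, five dilated
#' causal temporal blocks (64 channels, kernel 8, dilations 1, 2, 4, 8, 16,
#' dropout 0.2) and a 1x1 head over 4 classes. This configuration has
#' exactly 1,922,397 trainable parameters.
#'
#' @param epoch_len samples per 30-s epoch after resampling (default 1024).
#' @param n_epochs epochs per standardized recording (default 1200 = 10 h).
#' @param attention_channels channels of the attention causal convolution.
#' @param stem_channels,stem_kernel,stem_stride stem convolution geometry.
#' @param inception_in per-block input channel counts.
#' @param inception_filters per-branch filter counts (each block emits
#'   `4 * filters` channels: three convolution branches plus a max-pool
#'   projection branch).
#' @param inception_bottleneck per-block bottleneck widths.
#' @param inception_kernels the three branch kernel sizes.
#' @param post_channels channels of the 1x1 convolution that closes the
#'   Inception module after adaptive pooling.
#' @param tdd_width width of the time-distributed dense layer.
#' @param tcn_blocks,tcn_channels,tcn_kernel,tcn_dilations,tcn_dropout
#'   temporal-stack geometry.
#' @param n_classes number of output classes (4: wake, light, deep, REM).
#' @param init_seed seed used for weight initialization.
#' @return an object of class `model_config`.
#' @export
model_config <- function(epoch_len = 1024L,
                         n_epochs = 1200L,
                         attention_channels = 128L,
                         stem_channels = 32L,
                         stem_kernel = 40L,
                         stem_stride = 20L,
                         inception_in = c(32L, 32L, 64L, 64L, 128L, 256L),
                         inception_filters = c(8L, 16L, 16L, 32L, 64L, 128L),
                         inception_bottleneck = c(8L, 16L, 16L, 16L, 32L, 32L),
                         inception_kernels = c(5L, 11L, 23L),
                         post_channels = 256L,
                         tdd_width = 64L,
                         tcn_blocks = 5L,
                         tcn_channels = 64L,
                         tcn_kernel = 8L,
                         tcn_dilations = c(1L, 2L, 4L, 8L, 16L),
                         tcn_dropout = 0.2,
                         n_classes = 4L,
                         init_seed = 1L) {
  cfg <- list(
    epoch_len = as.integer(epoch_len),
    n_epochs = as.integer(n_epochs),
    attention_kernel = 7L * as.integer(epoch_len),
    attention_channels = as.integer(attention_channels),
    stem_channels = as.integer(stem_channels),
    stem_kernel = as.integer(stem_kernel),
    stem_stride = as.integer(stem_stride),
    inception_in = as.integer(inception_in),
    inception_filters = as.integer(inception_filters),
    inception_bottleneck = as.integer(inception_bottleneck),
    inception_kernels = as.integer(inception_kernels),
    post_channels = as.integer(post_channels),
    tdd_width = as.integer(tdd_width),
    tcn_blocks = as.integer(tcn_blocks),
    tcn_channels = as.integer(tcn_channels),
    tcn_kernel = as.integer(tcn_kernel),
    tcn_dilations = as.integer(tcn_dilations),
    tcn_dropout = tcn_dropout,
    n_classes = as.integer(n_classes),
    init_seed = as.integer(init_seed)
  )
  class(cfg) <- "model_config"
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  nb <- length(cfg$inception_in)
  if (length(cfg$inception_filters) != nb ||
      length(cfg$inception_bottleneck) != nb) {
    stop_insight("inception_in, inception_filters and inception_bottleneck ",
                 "must have equal length")
  }
  if (cfg$attention_kernel != 7L * cfg$epoch_len) {
    stop_insight("attention kernel must span exactly 7 epochs")
  }
  if (cfg$inception_in[1] != cfg$stem_channels) {
    stop_insight("first Inception block must accept the stem channel count")
  }
  out <- 4L * cfg$inception_filters
  if (nb > 1 && any(out[-nb] != cfg$inception_in[-1])) {
    stop_insight("Inception channel chain broken: block b emits 4*filters_b ",
                 "channels which must equal inception_in[b+1]")
  }
  if (length(cfg$inception_kernels) != 3L) {
    stop_insight("exactly three branch kernels are expected")
  }
  if (length(cfg$tcn_dilations) != cfg$tcn_blocks) {
    stop_insight("one dilation per temporal block is required")
  }
  if (cfg$tcn_blocks > 1 &&
      any(cfg$tcn_dilations[-1] != 2L * cfg$tcn_dilations[-cfg$tcn_blocks])) {
    stop_insight("temporal-block dilations must double: 1, 2, 4, ...")
  }
  if ((cfg$epoch_len * cfg$n_epochs) %% cfg$stem_stride != 0) {
    stop_insight("input length must be divisible by the stem stride")
  }
  if (cfg$tcn_dropout < 0 || cfg$tcn_dropout >= 1) {
    stop_insight("tcn_dropout must lie in [0, 1)")
  }
  invisible(cfg)
}

#' Reduced-width configuration for desk-scale experiments
#'
#' A small instance of the same architecture (identical wiring, narrower
#' channels, fewer blocks, shorter grid) used by the training and causality
#' test suites where the full 1.9M-parameter network would be needlessly
#' expensive.
#'
#' @param epoch_len samples per epoch (default 1024, so real preprocessed
#'   recordings can be fed unchanged).
#' @param n_epochs epochs per input (default 120, a 1-h grid).
#' @param init_seed seed for weight initialization.
#' @return a `model_config`.
#' @export
reduced_model_config <- function(epoch_len = 1024L, n_epochs = 120L,
                                 init_seed = 1L) {
  model_config(
    epoch_len = epoch_len,
    n_epochs = n_epochs,
    attention_channels = 4L,
    stem_channels = 8L,
    stem_kernel = 40L,
    stem_stride = 20L,
    inception_in = c(8L, 8L, 16L, 16L),
    inception_filters = c(2L, 4L, 4L, 8L),
    inception_bottleneck = c(2L, 2L, 2L, 4L),
    post_channels = 16L,
    tdd_width = 16L,
    tcn_blocks = 3L,
    tcn_channels = 16L,
    tcn_kernel = 4L,
    tcn_dilations = c(1L, 2L, 4L),
    init_seed = init_seed
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  grid       : %d epochs x %d samples\n", x$n_epochs, x$epoch_len))
  cat(sprintf("  attention  : causal k=%d, %d channels\n",
              x$attention_kernel, x$attention_channels))
  cat(sprintf("  stem       : %d ch, k=%d, stride %d\n",
              x$stem_channels, x$stem_kernel, x$stem_stride))
  cat(sprintf("  inception  : %d blocks, in [%s], filters [%s]\n",
              length(x$inception_in),
              paste(x$inception_in, collapse = ","),
              paste(x$inception_filters, collapse = ",")))
  cat(sprintf("  post/tdd   : 1x1 -> %d, dense -> %d\n",
              x$post_channels, x$tdd_width))
  cat(sprintf("  tcn        : %d blocks, %d ch, k=%d, dilations [%s]\n",
              x$tcn_blocks, x$tcn_channels, x$tcn_kernel,
              paste(x$tcn_dilations, collapse = ",")))
  cat(sprintf("  classes    : %d\n", x$n_classes))
  invisible(x)
}
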
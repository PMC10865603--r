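# Plotting helpers (ggplot2).

#' Plot a hypnogram
#'
#' Step plot of the per-epoch stage sequence, wake on top and deep sleep at
#' the bottom, as sleep clinicians draw them.
#'
#' @param labels a [four_class_labels()] or [stage_sequence()].
#' @return a ggplot object.
#' @export
plot_hypnogram <- function(labels) {
  if (inherits(labels, "stage_sequence")) labels <- map_rk_to_four(labels)
  y <- labels$labels
  df <- data.frame(hours = (seq_along(y) - 1) * 30 / 3600,
                   stage = factor(four_token(y),
                                  levels = rev(c("wake", "rem", "light",
                                                 "deep"))))
  df <- df[labels$mask, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours,
                                   y = as.integer(.data$stage))) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = 1:4,
                                labels = levels(df$stage),
                                limits = c(0.5, 4.5)) +
    ggplot2::labs(x = "time (h)", y = NULL, title = "Hypnogram") +
    ggplot2::theme_minimal()
}

#' Plot an attention map over a signal excerpt
#'
#' Overlays the min-max normalized per-sample attention on the input
#' waveform for a chosen epoch, the view used to inspect what the attention
#' gate emphasizes (typically the pulse peaks).
#'
#' @param attention an `attention_map` from [extract_attention()].
#' @param input the matching [epochized_input()].
#' @param epoch which epoch to display (default 1).
#' @return a ggplot object.
#' @export
plot_attention <- function(attention, input, epoch = 1L) {
  stopifnot(inherits(attention, "attention_map"),
            inherits(input, "epochized_input"))
  len <- ncol(input$values)
  idx <- ((epoch - 1) * len + 1):(epoch * len)
  df <- data.frame(t = rep(seq_len(len) / len * 30, 2),
                   value = c(input$values[epoch, ],
                             attention$normalized[idx]),
                   series = rep(c("PPG", "attention"), each = len))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time within epoch (s)", y = NULL,
                  title = sprintf("Epoch %d attention", epoch)) +
    ggplot2::theme_minimal()
}
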
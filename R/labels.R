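# Stage label handling: R&K 6-class scorings, the 4-class training scheme
# (wake / light / deep / REM), and inverse-frequency class weights.

RK6_LEVELS <- c("W", "S1", "S2", "S3", "S4", "R")
FOUR_LEVELS <- c("wake", "light", "deep", "rem")
UNSCORED <- "unscored"

#' Stage-label sequence
#'
#' A per-epoch sequence of sleep-stage labels on the fixed 30-s epoch grid.
#' Supported schemes: `RK6` (Rechtschaffen & Kales W, S1-S4, R) and `FOUR`
#' (wake, light, deep, rem). The sentinel `"unscored"` marks epochs without
#' a valid score (including movement-time / artifact codes).
#'
#' @param labels character vector of stage codes.
#' @param scheme `"RK6"` or `"FOUR"`.
#' @return object of class `stage_sequence`.
#' @export
stage_sequence <- function(labels, scheme = c("RK6", "FOUR")) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  valid <- c(switch(scheme, RK6 = RK6_LEVELS, FOUR = FOUR_LEVELS), UNSCORED)
  bad <- setdiff(unique(labels), valid)
  if (length(bad) > 0) {
    stop_insight("unknown stage label token(s): ", paste(bad, collapse = ", "),
                 class = "insightsleep_label_error")
  }
  structure(list(labels = labels, scheme = scheme, epoch_seconds = 30),
            class = "stage_sequence")
}

#' @export
print.stage_sequence <- function(x, ...) {
  cat(sprintf("<stage_sequence> %s, %d epochs (30 s each)\n",
              x$scheme, length(x$labels)))
  invisible(x)
}

#' @export
length.stage_sequence <- function(x) length(x$labels)

#' Map an R&K 6-class scoring to the 4-class scheme
#'
#' W maps to wake; S1 and S2 are grouped as light sleep; S3 and S4 are
#' consolidated as deep sleep; R maps to REM. Unscored epochs become the
#' ignore sentinel (NA label, mask FALSE). The mapping is total and, applied
#' to FOUR-scheme input, the identity.
#'
#' @param stages a [stage_sequence()] with scheme `RK6` (or `FOUR`, returned
#'   unchanged).
#' @return object of class `four_class_labels`: integer labels with the
#'   frozen encoding wake=0, light=1, deep=2, rem=3 (NA = ignore) and a
#'   logical `mask`.
#' @export
map_rk_to_four <- function(stages) {
  stopifnot(inherits(stages, "stage_sequence"))
  map <- if (stages$scheme == "RK6") {
    c(W = 0L, S1 = 1L, S2 = 1L, S3 = 2L, S4 = 2L, R = 3L)
  } else {
    c(wake = 0L, light = 1L, deep = 2L, rem = 3L)
  }
  idx <- unname(map[stages$labels])  # unscored -> NA
  four_class_labels(idx, !is.na(idx))
}

#' Four-class label container
#'
#' @param labels integer vector over 0 (wake), 1 (light), 2 (deep), 3 (rem);
#'   NA for ignored epochs.
#' @param mask logical vector, FALSE where the label is to be ignored
#'   (unscored or padding).
#' @return object of class `four_class_labels`.
#' @export
four_class_labels <- function(labels, mask = !is.na(labels)) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(mask))
  if (any(labels[!is.na(labels)] < 0L | labels[!is.na(labels)] > 3L)) {
    stop_insight("four-class labels must lie in 0..3")
  }
  mask <- as.logical(mask) & !is.na(labels)
  structure(list(labels = labels, mask = mask), class = "four_class_labels")
}

#' @export
length.four_class_labels <- function(x) length(x$labels)

#' Align labels to a fixed epoch grid
#'
#' Truncates label sequences longer than `n_epochs` (the initial epochs are
#' kept) and pads shorter ones with the ignore sentinel, mirroring
#' [standardize_length()] on the signal side.
#'
#' @param labels a `four_class_labels`.
#' @param n_epochs grid length (default 1200).
#' @return a `four_class_labels` of length `n_epochs`.
#' @export
align_labels <- function(labels, n_epochs = 1200L) {
  stopifnot(inherits(labels, "four_class_labels"))
  n <- length(labels$labels)
  if (n >= n_epochs) {
    four_class_labels(labels$labels[seq_len(n_epochs)],
                      labels$mask[seq_len(n_epochs)])
  } else {
    four_class_labels(c(labels$labels, rep(NA_integer_, n_epochs - n)),
                      c(labels$mask, rep(FALSE, n_epochs - n)))
  }
}

#' Inverse-frequency class weights
#'
#' weight_k = N_total / (K * N_k) over masked-in epochs, so balanced classes
#' get unit weights and sum_k weight_k * N_k equals N_total (the weighted
#' epoch count matches the raw count). Masked-out epochs never influence the
#' weights.
#'
#' @param labels a `four_class_labels`, or a list of them pooled over a
#'   training set.
#' @return numeric vector of 4 positive weights (wake, light, deep, rem).
#' @export
class_weights <- function(labels) {
  if (inherits(labels, "four_class_labels")) labels <- list(labels)
  y <- unlist(lapply(labels, function(l) l$labels[l$mask]))
  counts <- tabulate(y + 1L, nbins = 4L)
  if (any(counts == 0)) {
    stop_insight("every class must be present at least once; missing: ",
                 paste(FOUR_LEVELS[counts == 0], collapse = ", "))
  }
  length(y) / (4 * counts)
}

four_token <- function(idx) ifelse(is.na(idx), UNSCORED, FOUR_LEVELS[idx + 1L])
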
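# Signal conditioning: low-pass filter, polynomial detrend, min-max
# normalization, resampling to the 1024-samples-per-epoch grid, and length
# standardization to the fixed 1200-epoch input. Steps are applied in that
# frozen order by preprocess_pipeline().

#' PPG record container
#'
#' @param subject_id character identifier.
#' @param signal numeric sample vector (arbitrary physical units).
#' @param fs sampling rate in Hz, > 0.
#' @param start_time optional start timestamp (character).
#' @return object of class `ppg_record`.
#' @export
ppg_record <- function(subject_id, signal, fs, start_time = NULL) {
  signal <- as.numeric(signal)
  if (length(signal) < 1) stop_insight("signal must contain >= 1 sample")
  if (!is.numeric(fs) || fs <= 0) stop_insight("fs must be > 0")
  if (any(!is.finite(signal))) {
    stop_insight("signal contains non-finite samples; repair first ",
                 "(see repair_nonfinite)")
  }
  structure(list(subject_id = as.character(subject_id), signal = signal,
                 fs = fs, start_time = start_time),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %s: %d samples @ %g Hz (%.2f h)\n",
              x$subject_id, length(x$signal), x$fs,
              length(x$signal) / x$fs / 3600))
  invisible(x)
}

#' Repair non-finite samples
#'
#' Isolated non-finite samples (NA/NaN/Inf) are replaced by linear
#' interpolation between their finite neighbours; records with more than
#' `max_bad_fraction` non-finite samples are rejected. Leading/trailing
#' non-finite runs take the nearest finite value.
#'
#' @param signal numeric vector.
#' @param max_bad_fraction rejection threshold (default 0.05).
#' @return repaired numeric vector.
#' @export
repair_nonfinite <- function(signal, max_bad_fraction = 0.05) {
  bad <- !is.finite(signal)
  if (!any(bad)) return(signal)
  if (mean(bad) > max_bad_fraction) {
    stop_insight(sprintf("%.1f%% of samples are non-finite (limit %.1f%%)",
                         100 * mean(bad), 100 * max_bad_fraction))
  }
  if (all(bad)) stop_insight("all samples non-finite")
  idx <- seq_along(signal)
  stats::approx(idx[!bad], signal[!bad], xout = idx, rule = 2)$y
}

#' Zero-phase Chebyshev type II low-pass filter
#'
#' 8th-order Chebyshev type II design with stop-band edge 8 Hz and 40 dB
#' stop-band attenuation, applied forward and backward (filtfilt) so the
#' result has no group delay.
#'
#' @param record a [ppg_record()] with `fs > 16` Hz.
#' @param cutoff stop-band edge in Hz (default 8).
#' @param order filter order (default 8).
#' @param stopband_db stop-band attenuation in dB (default 40).
#' @return filtered `ppg_record` of identical length and rate.
#' @export
lowpass_filter <- function(record, cutoff = 8, order = 8, stopband_db = 40) {
  stopifnot(inherits(record, "ppg_record"))
  if (record$fs <= 2 * cutoff) {
    stop_insight("sampling rate must exceed twice the cutoff (fs > ",
                 2 * cutoff, " Hz)")
  }
  ba <- signal::cheby2(order, stopband_db, cutoff / (record$fs / 2),
                       type = "low")
  y <- zero_phase_filter(ba$b, ba$a, record$signal)
  ppg_record(record$subject_id, y, record$fs, record$start_time)
}

# Forward-backward IIR filtering with odd-reflection end padding, sized from
# the slowest filter pole so start-up transients decay inside the pads and
# a constant signal passes through bit-clean (up to the filter's unit DC
# gain). Plain zero padding would leak edge transients ~40% into the data.
zero_phase_filter <- function(b, a, x) {
  L <- length(x)
  rho <- max(Mod(polyroot(rev(a))))
  rho <- min(max(rho, 0.5), 0.99999)
  pl <- max(3L * length(a), ceiling(log(1e-13) / log(rho)))
  pl <- min(L - 1L, as.integer(pl))
  left <- 2 * x[1] - x[(pl + 1):2]
  right <- 2 * x[L] - x[(L - 1):(L - pl)]
  xp <- c(left, x, right)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pl + 1):(pl + L)]
}

# Legendre-recurrence design matrix on [-1, 1], accumulated in chunks so the
# full n x (order+1) basis is never materialized for multi-hour signals.
poly_detrend_fit <- function(x, order) {
  n <- length(x)
  gram <- matrix(0, order + 1, order + 1)
  rhs <- numeric(order + 1)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 1e6))
  basis_chunk <- function(idx) {
    t <- 2 * (idx - 1) / (n - 1) - 1
    P <- matrix(0, length(idx), order + 1)
    P[, 1] <- 1
    if (order >= 1) P[, 2] <- t
    if (order >= 2) {
      for (k in 2:order) {
        P[, k + 1] <- ((2 * k - 1) * t * P[, k] - (k - 1) * P[, k - 1]) / k
      }
    }
    P
  }
  for (idx in chunks) {
    P <- basis_chunk(idx)
    gram <- gram + crossprod(P)
    rhs <- rhs + crossprod(P, x[idx])
  }
  coef <- solve(gram, rhs)
  out <- numeric(n)
  for (idx in chunks) out[idx] <- x[idx] - basis_chunk(idx) %*% coef
  out
}

#' Polynomial detrending
#'
#' Subtracts the least-squares polynomial fit of the stated order (default
#' 10) over the full record. The abscissa is rescaled to [-1, 1] and the fit
#' uses a Legendre basis, so the normal equations stay well conditioned at
#' degree 10 over millions of samples; the fitted subspace is identical to
#' an ordinary power-basis fit.
#'
#' @param record a [ppg_record()].
#' @param order polynomial degree (default 10).
#' @return detrended `ppg_record`.
#' @export
detrend_polynomial <- function(record, order = 10) {
  stopifnot(inherits(record, "ppg_record"))
  if (length(record$signal) <= order + 1) {
    stop_insight("record too short for a degree-", order, " fit")
  }
  y <- poly_detrend_fit(record$signal, order)
  ppg_record(record$subject_id, y, record$fs, record$start_time)
}

#' Min-max normalization to [0, 1]
#'
#' (x - min) / (max - min) over the whole record. Statistics are computed
#' per recording, not per epoch, so amplitude dynamics across the night are
#' preserved.
#'
#' @param record a [ppg_record()] with non-constant signal.
#' @return normalized `ppg_record` with min 0 and max 1.
#' @export
minmax_normalize <- function(record) {
  stopifnot(inherits(record, "ppg_record"))
  r <- range(record$signal)
  if (diff(r) == 0) {
    stop_insight("constant signal cannot be min-max normalized",
                 class = "insightsleep_degenerate_error")
  }
  ppg_record(record$subject_id, (record$signal - r[1]) / diff(r),
             record$fs, record$start_time)
}

rational_approx <- function(x, max_den = 10000L) {
  # continued-fraction expansion
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r - a < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p = as.integer(p1), q = as.integer(q1))
}

#' Resample to the 1024-samples-per-epoch grid
#'
#' Polyphase rational resampling (upsample, windowed-sinc anti-alias FIR,
#' downsample) to an effective rate of 1024/30 Hz (34.133... Hz), so every
#' 30-s epoch holds exactly 1024 samples. A trailing partial epoch is
#' discarded.
#'
#' @param record a [ppg_record()] at least one epoch (30 s) long, `fs` at or
#'   above the target rate.
#' @param samples_per_epoch target samples per 30-s epoch (default 1024).
#' @return `ppg_record` at the epoch-grid rate whose length is a multiple of
#'   `samples_per_epoch`.
#' @export
resample_to_epoch_grid <- function(record, samples_per_epoch = 1024L) {
  stopifnot(inherits(record, "ppg_record"))
  target_fs <- samples_per_epoch / 30
  if (record$fs < target_fs) {
    stop_insight("fs below the epoch-grid target rate")
  }
  n_full <- floor(length(record$signal) / record$fs / 30)
  if (n_full < 1) stop_insight("record shorter than one 30-s epoch")
  pq <- rational_approx(target_fs / record$fs)
  p <- pq["p"]; q <- pq["q"]
  # windowed-sinc low-pass at the post-decimation Nyquist, gain p
  half_width <- 10L
  nh <- 2L * half_width * max(p, q) + 1L
  m <- seq_len(nh) - 1 - (nh - 1) / 2
  fc <- 1 / (2 * max(p, q))  # cycles per (upsampled) sample
  hsinc <- 2 * fc * sinc_fn(2 * fc * m)
  win <- 0.54 + 0.46 * cos(2 * pi * m / (nh - 1))
  h <- p * hsinc * win
  n_out <- n_full * samples_per_epoch
  y <- cpp_upfirdn(record$signal, h, as.integer(p), as.integer(q),
                   as.integer(n_out))
  ppg_record(record$subject_id, y, target_fs, record$start_time)
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Epochized model input
#'
#' The fixed-shape network input: `n_epochs` x `samples_per_epoch` values in
#' [0, 1], a prefix-true epoch mask (padding is appended at the end and is
#' exactly zero) and the count of valid epochs.
#'
#' @param values numeric matrix, `n_epochs` x `samples_per_epoch`.
#' @param n_valid_epochs number of real (non-padding) epochs.
#' @return object of class `epochized_input`.
#' @export
epochized_input <- function(values, n_valid_epochs) {
  stopifnot(is.matrix(values))
  n_valid_epochs <- as.integer(n_valid_epochs)
  if (n_valid_epochs < 0 || n_valid_epochs > nrow(values)) {
    stop_insight("n_valid_epochs out of range")
  }
  if (any(values < 0 | values > 1)) {
    stop_insight("epochized values must lie in [0, 1]")
  }
  if (n_valid_epochs < nrow(values) &&
      any(values[(n_valid_epochs + 1):nrow(values), ] != 0)) {
    stop_insight("padded epochs must be exactly zero")
  }
  structure(list(values = values, n_valid_epochs = n_valid_epochs),
            class = "epochized_input")
}

#' @rdname epochized_input
#' @param x an `epochized_input`.
#' @export
epoch_mask <- function(x) {
  stopifnot(inherits(x, "epochized_input"))
  seq_len(nrow(x$values)) <= x$n_valid_epochs
}

#' @export
print.epochized_input <- function(x, ...) {
  cat(sprintf("<epochized_input> %d x %d (%d valid epochs)\n",
              nrow(x$values), ncol(x$values), x$n_valid_epochs))
  invisible(x)
}

#' Standardize a record to the fixed input grid
#'
#' Recordings longer than `n_epochs` epochs keep their initial `n_epochs`;
#' shorter ones are zero-padded at the end with a false mask.
#'
#' @param record a [ppg_record()] already on the epoch grid (length a
#'   multiple of `samples_per_epoch`, values in [0, 1]).
#' @param n_epochs grid length (default 1200, i.e. 10 h).
#' @param samples_per_epoch samples per epoch (default 1024).
#' @return an [epochized_input()].
#' @export
standardize_length <- function(record, n_epochs = 1200L,
                               samples_per_epoch = 1024L) {
  stopifnot(inherits(record, "ppg_record"))
  L <- length(record$signal)
  if (L %% samples_per_epoch != 0) {
    stop_insight("record length is not a multiple of ", samples_per_epoch,
                 "; resample to the epoch grid first")
  }
  n_have <- L %/% samples_per_epoch
  n_keep <- min(n_have, n_epochs)
  values <- matrix(0, n_epochs, samples_per_epoch)
  values[seq_len(n_keep), ] <-
    matrix(record$signal[seq_len(n_keep * samples_per_epoch)],
           nrow = n_keep, byrow = TRUE)
  epochized_input(values, n_keep)
}

#' Full preprocessing pipeline
#'
#' Low-pass filter, degree-10 polynomial detrend, per-recording min-max
#' normalization, rational resampling to 1024 samples per epoch, length
#' standardization - in that frozen order. Resampling can overshoot the
#' [0, 1] range by a fraction of a percent (sinc interpolation ringing);
#' such samples are clipped back to the range.
#'
#' @param record a raw [ppg_record()].
#' @param n_epochs standardized grid length (default 1200).
#' @param samples_per_epoch samples per epoch (default 1024).
#' @return an [epochized_input()].
#' @export
preprocess_pipeline <- function(record, n_epochs = 1200L,
                                samples_per_epoch = 1024L) {
  rec <- lowpass_filter(record)
  rec <- detrend_polynomial(rec)
  rec <- minmax_normalize(rec)
  rec <- resample_to_epoch_grid(rec, samples_per_epoch)
  rec$signal <- pmin(pmax(rec$signal, 0), 1)
  standardize_length(rec, n_epochs, samples_per_epoch)
}
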
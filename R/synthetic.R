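# Synthetic overnight PPG with stage-dependent pulse dynamics.
#
# The generator emulates what the real cohorts provide - a quasi-periodic
# pulse waveform whose beat rate and variability depend on sleep stage,
# R&K-scored hypnograms with realistic bout structure, and 8-10 h
# recordings at 128 or 256 Hz - so the whole pipeline is testable without
# clinical data. It emulates autonomic stage signatures (slower, steadier
# beats in deep sleep; faster, more variable beats in wake and REM;
# stronger respiratory amplitude modulation in non-REM); it does not model
# validated PPG morphology, artifacts or arrhythmia.

DEFAULT_TRANSITIONS <- local({
  P <- rbind(
    c(.952, .030, .012, .000, .000, .006),
    c(.060, .850, .082, .000, .000, .008),
    c(.022, .010, .927, .020, .005, .016),
    c(.008, .000, .056, .880, .050, .006),
    c(.006, .000, .040, .066, .885, .003),
    c(.032, .010, .030, .000, .000, .928))
  dimnames(P) <- list(RK6_LEVELS, RK6_LEVELS)
  P
})

DEFAULT_STAGE_PARAMS <- data.frame(
  stage = FOUR_LEVELS,
  bpm = c(72, 62, 56, 68),
  cv = c(0.10, 0.06, 0.03, 0.12),
  resp_depth = c(0.10, 0.25, 0.35, 0.15))

#' Synthetic-data configuration
#'
#' @param n_subjects number of recordings to generate.
#' @param duration_hours scalar or length-2 range; per-subject durations are
#'   drawn uniformly from the range (default 8-10 h, the cohort norm).
#' @param fs sampling rate, 128 or 256 Hz.
#' @param seed master seed; every random quantity (hypnogram, beat
#'   intervals, noise, durations) derives from it.
#' @param transitions 6x6 row-stochastic R&K transition matrix; the default
#'   is tuned for bout structure (self-transitions at or above 0.85) and
#'   long-run 4-class occupancy near wake 34% / light 39% / deep 12% /
#'   REM 11%.
#' @param stage_params data.frame with columns `stage`, `bpm`, `cv`,
#'   `resp_depth` for the four classes (S1/S2 and S3/S4 share their group's
#'   pulse parameters; the R&K split exists to exercise the label mapper).
#' @param noise_sd white-noise standard deviation (template peak = 1).
#' @param wander_amplitude,wander_period baseline-wander sinusoid.
#' @param resp_period respiratory modulation period in seconds.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 1L, duration_hours = c(8, 10),
                         fs = 128L, seed = 1L,
                         transitions = DEFAULT_TRANSITIONS,
                         stage_params = DEFAULT_STAGE_PARAMS,
                         noise_sd = 0.05, wander_amplitude = 0.3,
                         wander_period = 60, resp_period = 4) {
  if (!fs %in% c(128L, 256L)) stop_insight("fs must be 128 or 256 Hz")
  if (any(abs(rowSums(transitions) - 1) > 1e-8) || any(transitions < 0)) {
    stop_insight("transition matrix must be row-stochastic")
  }
  if (any(stage_params$bpm < 30 | stage_params$bpm > 120)) {
    stop_insight("beat rates must lie within 30-120 bpm")
  }
  if (length(duration_hours) == 1) duration_hours <- rep(duration_hours, 2)
  structure(list(n_subjects = as.integer(n_subjects),
                 duration_hours = duration_hours, fs = as.integer(fs),
                 seed = as.integer(seed), transitions = transitions,
                 stage_params = stage_params, noise_sd = noise_sd,
                 wander_amplitude = wander_amplitude,
                 wander_period = wander_period, resp_period = resp_period),
            class = "synth_config")
}

#' Generate a synthetic R&K hypnogram
#'
#' First-order Markov chain over the six R&K stages, starting in wake.
#'
#' @param config a [synth_config()].
#' @param n_epochs number of 30-s epochs.
#' @param seed optional override of `config$seed`.
#' @return a [stage_sequence()] with scheme RK6.
#' @export
generate_hypnogram <- function(config, n_epochs, seed = config$seed) {
  P <- config$transitions
  labels <- character(n_epochs)
  with_seed_local(seed, {
    state <- 1L
    for (e in seq_len(n_epochs)) {
      labels[e] <- RK6_LEVELS[state]
      state <- sample.int(6L, 1L, prob = P[state, ])
    }
  })
  stage_sequence(labels, "RK6")
}

# Asymmetric pulse template on phase [0, 1): sharp systolic upstroke with
# the peak near phase 0.22, then a dicrotic shoulder.
pulse_template <- function(phase) {
  exp(-0.5 * ((phase - 0.22) / 0.09)^2) +
    0.42 * exp(-0.5 * ((phase - 0.55) / 0.14)^2)
}

#' Generate a synthetic PPG signal for a hypnogram
#'
#' Beat onsets follow a stage-dependent renewal process (interval mean
#' 60/bpm, coefficient of variation per stage, truncated at 0.3 s); each
#' beat is a fixed asymmetric pulse template stretched to its interval,
#' amplitude-modulated by a respiration sinusoid (depth per stage), plus
#' slow baseline wander and white noise. The stage of a beat is that of the
#' epoch containing its onset.
#'
#' @param hypnogram a [stage_sequence()] (RK6 or FOUR).
#' @param config a [synth_config()].
#' @param seed optional override; defaults to `config$seed + 1` so the beat
#'   stream is independent of the hypnogram stream.
#' @return a [ppg_record()] with extra fields `peaks` (systolic peak sample
#'   indices) and `beats` (data.frame: onset seconds, interval, stage
#'   index) as generator metadata for downstream tests.
#' @export
generate_ppg <- function(hypnogram, config, seed = config$seed + 1L) {
  four <- map_rk_to_four(hypnogram)
  stage_of_epoch <- four$labels  # 0..3, NA never occurs from the generator
  n_epochs <- length(stage_of_epoch)
  total_s <- n_epochs * 30
  fs <- config$fs
  n <- total_s * fs
  sp <- config$stage_params
  x <- numeric(n)
  cap <- as.integer(total_s / 0.3) + 8L
  onsets <- numeric(cap); intervals <- numeric(cap); stages <- integer(cap)
  peaks <- integer(cap)
  n_beats <- 0L
  with_seed_local(seed, {
    t_cur <- 0
    while (t_cur < total_s) {
      ep <- min(n_epochs, floor(t_cur / 30) + 1)
      st <- stage_of_epoch[ep] + 1L
      mu <- 60 / sp$bpm[st]
      iv <- max(0.3, stats::rnorm(1, mu, sp$cv[st] * mu))
      n_beats <- n_beats + 1L
      onsets[n_beats] <- t_cur
      intervals[n_beats] <- iv
      stages[n_beats] <- st - 1L
      t_cur <- t_cur + iv
    }
    onsets <- onsets[seq_len(n_beats)]
    intervals <- intervals[seq_len(n_beats)]
    stages <- stages[seq_len(n_beats)]
    resp_amp <- 1 + sp$resp_depth[stages + 1L] *
      sin(2 * pi * onsets / config$resp_period)
    n_peaks <- 0L
    for (i in seq_len(n_beats)) {
      i0 <- floor(onsets[i] * fs)
      len <- max(2L, as.integer(round(intervals[i] * fs)))
      idx <- i0 + seq_len(len)
      idx <- idx[idx <= n]
      if (length(idx) == 0) next
      phase <- (seq_along(idx) - 1) / len
      x[idx] <- x[idx] + resp_amp[i] * pulse_template(phase)
      pk <- as.integer(i0) + which.max(pulse_template((seq_len(len) - 1) / len))
      if (pk <= n) { n_peaks <- n_peaks + 1L; peaks[n_peaks] <- pk }
    }
    peaks <- peaks[seq_len(n_peaks)]
    tt <- (seq_len(n) - 1) / fs
    if (config$wander_amplitude > 0) {
      x <- x + config$wander_amplitude *
        sin(2 * pi * tt / config$wander_period)
    }
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
  })
  rec <- ppg_record("synthetic", x, fs)
  rec$peaks <- peaks
  rec$beats <- data.frame(onset = onsets, interval = intervals,
                          stage = stages)
  rec
}

#' Write a synthetic dataset to disk
#'
#' Generates `n_subjects` recordings (per-subject seeds derived from the
#' master seed), writes each as a 16-bit EDF (channel label "Pleth") plus
#' an R&K label CSV, and a manifest CSV linking them.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if missing).
#' @return the manifest as a data.frame (columns `subject_id`, `edf_path`,
#'   `labels_path`, `n_epochs`), invisibly written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
make_dataset <- function(config, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_insight("cannot create directory ", dir)
  }
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("synth%03d", i)
    subj_seed <- (config$seed + i * 10007L) %% 2147483647L
    dur_h <- with_seed_local(subj_seed,
      stats::runif(1, config$duration_hours[1], config$duration_hours[2]))
    n_epochs <- floor(dur_h * 3600 / 30)
    hyp <- generate_hypnogram(config, n_epochs, seed = subj_seed + 1L)
    rec <- generate_ppg(hyp, config, seed = subj_seed + 2L)
    edf_path <- file.path(dir, paste0(sid, ".edf"))
    lab_path <- file.path(dir, paste0(sid, "_stages.csv"))
    write_edf(list(list(label = "Pleth", signal = rec$signal,
                        fs = config$fs)), edf_path)
    writeLines(hyp$labels, lab_path)
    rows[[i]] <- data.frame(subject_id = sid, edf_path = edf_path,
                            labels_path = lab_path, n_epochs = n_epochs)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
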
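# EDF input/output, stage-annotation parsing and prediction reports.
#
# The EDF reader/writer covers the classic 16-bit EDF/EDF+ layout
# (256-byte ASCII main header, 256 bytes per signal header, little-endian
# two-byte samples in integer-second data records) - the subset the
# polysomnography cohorts this package targets actually use. EDF+
# annotations-in-signal streams are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a minimal EDF file
#'
#' Writes one or more channels as 16-bit EDF with one-second data records.
#' Each channel is a list with `label`, `signal` and `fs` (samples per
#' second, integer); all channels must span the same whole number of
#' seconds (the signal is truncated to whole seconds).
#'
#' @param channels list of channel lists (`label`, `signal`, `fs`).
#' @param path output path.
#' @param patient_id,recording_id,start_date,start_time header strings.
#' @return invisibly, the path.
#' @export
write_edf <- function(channels, path, patient_id = "X", recording_id = "X",
                      start_date = "01.01.24", start_time = "22.00.00") {
  stopifnot(length(channels) >= 1)
  secs <- vapply(channels, function(ch) length(ch$signal) %/% ch$fs,
                 numeric(1))
  n_rec <- as.integer(min(secs))
  if (n_rec < 1) stop_insight("channels must span at least one second")
  ns <- length(channels)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient_id, 80), edf_pad(recording_id, 80),
    edf_pad(start_date, 8), edf_pad(start_time, 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(get, width) {
    paste0(vapply(channels, function(ch) edf_pad(get(ch), width),
                  character(1)), collapse = "")
  }
  ranges <- lapply(channels, function(ch) {
    r <- range(ch$signal)
    if (diff(r) == 0) r <- r + c(-1, 1)
    r
  })
  sig_hdr <- paste0(
    field(function(ch) ch$label, 16),
    field(function(ch) "", 80),
    field(function(ch) ch$unit %||% "uV", 8),
    paste0(vapply(ranges, function(r) edf_pad(formatC(r[1], digits = 6,
                                                      format = "g"), 8),
                  character(1)), collapse = ""),
    paste0(vapply(ranges, function(r) edf_pad(formatC(r[2], digits = 6,
                                                      format = "g"), 8),
                  character(1)), collapse = ""),
    field(function(ch) "-32768", 8),
    field(function(ch) "32767", 8),
    field(function(ch) "", 80),
    field(function(ch) as.integer(ch$fs), 8),
    field(function(ch) "", 32))
  writeChar(sig_hdr, con, eos = NULL)
  digital <- lapply(seq_along(channels), function(i) {
    ch <- channels[[i]]; r <- ranges[[i]]
    x <- ch$signal[seq_len(n_rec * ch$fs)]
    as.integer(round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768))
  })
  for (rec in seq_len(n_rec)) {
    for (i in seq_along(channels)) {
      fs <- channels[[i]]$fs
      writeBin(digital[[i]][((rec - 1) * fs + 1):(rec * fs)], con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  start_date <- rd(8); start_time <- rd(8)
  hdr_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur)) {
    stop_insight("corrupt EDF header", class = "insightsleep_edf_error")
  }
  per <- function(w, conv = identity) {
    vapply(seq_len(ns), function(i) conv(rd(w)), numeric(1))
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  transducer <- vapply(seq_len(ns), function(i) rd(80), character(1))
  unit <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- per(8, as.numeric); pmax <- per(8, as.numeric)
  dmin <- per(8, as.numeric); dmax <- per(8, as.numeric)
  prefilter <- vapply(seq_len(ns), function(i) rd(80), character(1))
  spr <- per(8, function(x) as.numeric(x))
  invisible(readChar(con, 32 * ns, useBytes = TRUE))  # per-signal reserved
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr)))) {
    stop_insight("corrupt EDF signal headers",
                 class = "insightsleep_edf_error")
  }
  list(start_date = start_date, start_time = start_time, n_rec = n_rec,
       rec_dur = rec_dur, ns = ns, labels = labels, pmin = pmin,
       pmax = pmax, dmin = dmin, dmax = dmax, spr = as.integer(spr))
}

#' Read a PPG channel from an EDF file
#'
#' Reads the full named channel and converts digital values to physical
#' units using the header calibration. Isolated non-finite samples (possible
#' with pathological calibration fields) are repaired by interpolation;
#' records with more than 5% bad samples are rejected.
#'
#' @param path EDF/EDF+ file path.
#' @param channel channel label (exact match after trimming).
#' @return a [ppg_record()] with the header's sampling rate.
#' @export
read_edf_ppg <- function(path, channel) {
  if (!is.character(path) || nchar(path) == 0 || !file.exists(path)) {
    stop_insight("EDF file not found: '", path, "'",
                 class = "insightsleep_missing_file_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_edf_header(con)
  idx <- match(channel, hdr$labels)
  if (is.na(idx)) {
    stop_insight("channel '", channel, "' not found; available: ",
                 paste(hdr$labels, collapse = ", "),
                 class = "insightsleep_channel_error")
  }
  spr <- hdr$spr
  out <- numeric(hdr$n_rec * spr[idx])
  offs <- c(0, cumsum(spr))
  for (rec in seq_len(hdr$n_rec)) {
    block <- readBin(con, "integer", n = sum(spr), size = 2,
                     endian = "little", signed = TRUE)
    if (length(block) < sum(spr)) {
      stop_insight("truncated EDF data records",
                   class = "insightsleep_edf_error")
    }
    out[((rec - 1) * spr[idx] + 1):(rec * spr[idx])] <-
      block[(offs[idx] + 1):offs[idx + 1]]
  }
  scale <- (hdr$pmax[idx] - hdr$pmin[idx]) / (hdr$dmax[idx] - hdr$dmin[idx])
  phys <- (out - hdr$dmin[idx]) * scale + hdr$pmin[idx]
  fs <- spr[idx] / hdr$rec_dur
  phys <- repair_nonfinite(phys)
  ppg_record(subject_id = basename(path), signal = phys, fs = fs,
             start_time = paste(hdr$start_date, hdr$start_time))
}

STAGE_SYNONYMS <- c(
  "W" = "W", "WAKE" = "W", "WK" = "W",
  "S1" = "S1", "N1" = "S1", "1" = "S1",
  "S2" = "S2", "N2" = "S2", "2" = "S2",
  "S3" = "S3", "3" = "S3",
  "S4" = "S4", "4" = "S4",
  "R" = "R", "REM" = "R",
  "MT" = "unscored", "M" = "unscored", "?" = "unscored",
  "UNSCORED" = "unscored")

normalize_stage_tokens <- function(tokens) {
  key <- toupper(trimws(tokens))
  key[key == "?"] <- "?"
  mapped <- STAGE_SYNONYMS[key]
  bad <- is.na(mapped)
  if (any(bad)) {
    stop_insight("unknown stage label token(s): ",
                 paste(unique(tokens[bad]), collapse = ", "),
                 class = "insightsleep_label_error")
  }
  unname(mapped)
}

#' Read stage annotations
#'
#' Two dialects are supported. `csv_epochs`: one R&K label per line (W, S1,
#' S2, S3, S4, R and common synonyms; movement-time codes map to the
#' unscored sentinel). `xml_events`: a minimal scored-event list of
#' `<ScoredEvent>` elements with `<Stage>`, `<Start>` and `<Duration>`
#' children (seconds from recording start); each 30-s epoch takes the label
#' of the event covering at least 15 s of it, ties going to the
#' earlier-starting event, and epochs without such cover are unscored.
#' Overlapping events with contradictory stages are an error.
#'
#' @param path annotation file.
#' @param dialect `"csv_epochs"` or `"xml_events"`.
#' @return a [stage_sequence()] with scheme RK6.
#' @export
read_stage_annotations <- function(path, dialect = c("csv_epochs",
                                                     "xml_events")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_insight("annotation file not found: ", path,
                 class = "insightsleep_missing_file_error")
  }
  if (dialect == "csv_epochs") {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    lines <- unlist(strsplit(lines, ","))
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    return(stage_sequence(normalize_stage_tokens(lines), "RK6"))
  }
  doc <- xml2::read_xml(path)
  ev <- xml2::xml_find_all(doc, ".//ScoredEvent")
  if (length(ev) == 0) stop_insight("no ScoredEvent elements found")
  stage <- normalize_stage_tokens(
    xml2::xml_text(xml2::xml_find_first(ev, "./Stage")))
  start <- as.numeric(xml2::xml_text(xml2::xml_find_first(ev, "./Start")))
  dur <- as.numeric(xml2::xml_text(xml2::xml_find_first(ev, "./Duration")))
  if (any(is.na(start)) || any(is.na(dur))) {
    stop_insight("events need numeric Start and Duration")
  }
  o <- order(start)
  stage <- stage[o]; start <- start[o]; dur <- dur[o]
  end <- start + dur
  if (length(ev) > 1) {
    for (i in 2:length(ev)) {
      overlap <- which(end[1:(i - 1)] > start[i] & stage[1:(i - 1)] != stage[i])
      if (length(overlap) > 0) {
        stop_insight("overlapping contradictory events at t=", start[i],
                     " s", class = "insightsleep_label_error")
      }
    }
  }
  n_epochs <- floor(max(end) / 30)
  labels <- rep("unscored", n_epochs)
  for (e in seq_len(n_epochs)) {
    lo <- (e - 1) * 30; hi <- e * 30
    cover <- pmin(end, hi) - pmax(start, lo)
    cand <- which(cover >= 15)
    if (length(cand) > 0) labels[e] <- stage[cand[1]]  # earlier event wins
  }
  stage_sequence(labels, "RK6")
}

#' Write / read a predictions report
#'
#' Emits an RFC-4180 CSV (UTF-8, '.' decimal separator) with columns
#' `epoch_index`, `predicted_stage`, `energy`, `accepted`,
#' `attention_score`, one row per masked-in epoch. Rejected epochs carry the
#' literal token `REJECT` in `predicted_stage`. Numeric columns are written
#' with 6 decimals and round-trip losslessly at that precision.
#'
#' @param result a `selective_result` from [selective_predict()].
#' @param path output path.
#' @param attention optional per-epoch attention scores (same length).
#' @return invisibly, the path.
#' @export
write_predictions <- function(result, path, attention = NULL) {
  stopifnot(inherits(result, "selective_result"))
  keep <- !is.na(result$accepted)
  if (sum(keep) < 1) stop_insight("no masked-in epochs to write")
  df <- result[keep, ]
  stage <- ifelse(df$accepted, four_token(df$predicted), "REJECT")
  att <- if (is.null(attention)) rep(NA_real_, nrow(result))
         else attention
  out <- data.frame(
    epoch_index = df$epoch,
    predicted_stage = stage,
    energy = sprintf("%.6f", df$energy),
    accepted = ifelse(df$accepted, "TRUE", "FALSE"),
    attention_score = sprintf("%.6f", att[keep]))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_insight("cannot write predictions to ", path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) {
    stop_insight("predictions file not found: ", path,
                 class = "insightsleep_missing_file_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$energy <- as.numeric(df$energy)
  df$attention_score <- suppressWarnings(as.numeric(df$attention_score))
  df$accepted <- as.logical(df$accepted)
  df
}
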
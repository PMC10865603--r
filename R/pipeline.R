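# End-to-end conveniences tying the modules together: whole-night
# prediction with selective rejection, dataset loading from manifests, and
# per-night evaluation reports.

#' Predict a night with selective rejection
#'
#' Eval-mode forward pass, per-epoch energies, acceptance under tau, and
#' the per-epoch attention aggregate in one call.
#'
#' @param model a `sleep_model`.
#' @param input an [epochized_input()].
#' @param tau energy threshold (default Inf: accept everything).
#' @param temperature energy/softmax temperature.
#' @return a `selective_result` data.frame (see [selective_predict()]) with
#'   an extra `attention_score` column.
#' @export
predict_night <- function(model, input, tau = Inf, temperature = 1) {
  stopifnot(inherits(input, "epochized_input"))
  out <- insight_forward(model, input)
  res <- selective_predict(out$logits, epoch_mask(input), tau, temperature)
  res$attention_score <-
    colMeans(matrix(out$attention, nrow = model$config$epoch_len))
  res
}

#' Load a synthetic (or real) dataset from a manifest
#'
#' Reads each manifest row's EDF + label CSV, runs the preprocessing
#' pipeline and aligns labels to the model grid.
#'
#' @param manifest data.frame with `edf_path` and `labels_path` columns (as
#'   written by [make_dataset()]), or a path to such a CSV.
#' @param channel EDF channel label (default "Pleth").
#' @param n_epochs,samples_per_epoch target grid.
#' @return list of `list(subject_id, input, labels)` entries ready for
#'   [train_loop()].
#' @export
load_dataset <- function(manifest, channel = "Pleth", n_epochs = 1200L,
                         samples_per_epoch = 1024L) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_edf_ppg(manifest$edf_path[i], channel)
    input <- preprocess_pipeline(rec, n_epochs, samples_per_epoch)
    stages <- read_stage_annotations(manifest$labels_path[i], "csv_epochs")
    labels <- align_labels(map_rk_to_four(stages), n_epochs)
    # epochs lost to padding/truncation on the signal side are masked out
    labels$mask <- labels$mask & (seq_len(n_epochs) <= input$n_valid_epochs)
    list(subject_id = manifest$subject_id[i], input = input,
         labels = labels)
  })
}

#' Evaluate predictions for a set of nights
#'
#' Pools epochs across subjects (the default) and reports metrics plus
#' per-subject sleep parameters for predictions and truth.
#'
#' @param results list of `selective_result` objects, one per subject.
#' @param truths list of `four_class_labels`, aligned.
#' @param per_subject also return a per-subject metric list.
#' @return list with `metrics` (pooled [metric_report()]), `parameters`
#'   (data.frame of per-subject predicted and true sleep parameters) and
#'   optionally `subjects`.
#' @export
evaluate_nights <- function(results, truths, per_subject = FALSE) {
  stopifnot(length(results) == length(truths))
  pred <- unlist(lapply(results, `[[`, "predicted"))
  acc <- unlist(lapply(results, `[[`, "accepted"))
  truth <- unlist(lapply(truths, `[[`, "labels"))
  mask <- unlist(lapply(truths, `[[`, "mask"))
  metrics <- metric_report(pred, truth, mask, acc)
  pars <- do.call(rbind, lapply(seq_along(results), function(i) {
    est <- sleep_parameters(results[[i]]$predicted, truths[[i]]$mask,
                            results[[i]]$accepted)
    tru <- sleep_parameters(truths[[i]], accepted = results[[i]]$accepted)
    data.frame(subject = i,
               est_tst = est$tst_minutes, est_light = est$fr_light,
               est_deep = est$fr_deep, est_rem = est$fr_rem,
               true_tst = tru$tst_minutes, true_light = tru$fr_light,
               true_deep = tru$fr_deep, true_rem = tru$fr_rem)
  }))
  out <- list(metrics = metrics, parameters = pars)
  if (per_subject) {
    out$subjects <- lapply(seq_along(results), function(i) {
      metric_report(results[[i]]$predicted, truths[[i]]$labels,
                    truths[[i]]$mask, results[[i]]$accepted)
    })
  }
  out
}
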
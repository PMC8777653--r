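#' Confusion counts for per-minute apnea predictions
#'
#' Apnea (`"A"`) is the positive class: `tp` counts minutes correctly
#' identified as apnea, `tn` minutes correctly identified as normal, `fp`
#' and `fn` the two error types. The four counts partition the minutes.
#'
#' @param predictions,truths Equal-length character vectors over
#'   `"A"`/`"N"`.
#' @return One-row tibble of class `confusion_counts` with columns
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion(c("A", "A", "N", "N"), c("A", "N", "N", "A"))
#' @export
confusion <- function(predictions, truths) {
  predictions <- check_labels(predictions, "predictions")
  truths <- check_labels(truths, "truths")
  if (length(predictions) != length(truths)) {
    abort(sprintf("length mismatch: %d predictions vs %d truths.",
                  length(predictions), length(truths)))
  }
  out <- tibble(
    tp = sum(predictions == "A" & truths == "A"),
    tn = sum(predictions == "N" & truths == "N"),
    fp = sum(predictions == "A" & truths == "N"),
    fn = sum(predictions == "N" & truths == "A")
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `Acc = (TP + TN) / (TP + TN + FP + FN)`, `Sen = TP / (TP + FN)`,
#' `Spec = TN / (TN + FP)`, all as percentages. A metric whose denominator
#' is zero is reported as `NA` (undefined) with a warning — never coerced to
#' 0 or 100.
#'
#' @param counts A [confusion()] result (or any one-row data frame with
#'   columns `tp`, `tn`, `fp`, `fn`).
#' @param granularity `"per_minute"` or `"per_recording"` (bookkeeping
#'   only).
#' @return One-row tibble: `acc`, `sen`, `spec` (percent), `granularity`.
#' @export
metrics <- function(counts, granularity = c("per_minute", "per_recording")) {
  granularity <- match.arg(granularity)
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  tp <- counts$tp[1]; tn <- counts$tn[1]
  fp <- counts$fp[1]; fn <- counts$fn[1]
  if (min(tp, tn, fp, fn) < 0) abort("confusion counts must be non-negative.")
  total <- tp + tn + fp + fn
  if (total == 0) abort("confusion counts sum to zero; no events to score.")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (denominator 0); reported as NA.", what))
      return(NA_real_)
    }
    100 * num / den
  }
  tibble(
    acc = 100 * (tp + tn) / total,
    sen = ratio(tp, tp + fn, "sensitivity"),
    spec = ratio(tn, tn + fp, "specificity"),
    granularity = granularity
  )
}

#' Per-recording OSA diagnosis from per-minute predictions
#'
#' The apnea-hypopnea index is approximated as predicted apnea minutes per
#' hour, `AHI = 60 * apnea_minutes / total_minutes`, a rate rather than a
#' whole-hour count so recordings of any length are handled uniformly. A
#' recording with AHI greater than or equal to 5 is diagnosed as OSA.
#'
#' @param predictions Character vector of per-minute predictions for one
#'   recording (`"A"`/`"N"`, at least one minute).
#' @param record_id Recording identifier carried into the result.
#' @return One-row tibble: `record_id`, `predicted_apnea_minutes`,
#'   `total_minutes`, `ahi`, `osa_flag`.
#' @examples
#' diagnose_recording(rep(c("A", "N"), c(30, 330)), "demo")  # AHI 5 -> OSA
#' @export
diagnose_recording <- function(predictions, record_id = "recording") {
  predictions <- check_labels(predictions, "predictions")
  if (length(predictions) == 0L) {
    abort("cannot diagnose a recording with no predicted minutes.")
  }
  apnea <- sum(predictions == "A")
  total <- length(predictions)
  ahi <- 60 * apnea / total
  tibble(
    record_id = as.character(record_id),
    predicted_apnea_minutes = apnea,
    total_minutes = total,
    ahi = ahi,
    osa_flag = ahi >= 5
  )
}

#' Reference OSA status of a recording from its annotations
#'
#' Applies the same AHI rule as [diagnose_recording()] to the reference
#' annotations, making predicted and true per-recording status commensurate.
#'
#' @param minute_labels Character vector of reference labels.
#' @return Logical: `TRUE` if the annotated AHI is >= 5.
#' @export
recording_truth <- function(minute_labels) {
  minute_labels <- check_labels(minute_labels)
  if (length(minute_labels) == 0L) {
    abort("cannot derive OSA status from zero annotated minutes.")
  }
  60 * sum(minute_labels == "A") / length(minute_labels) >= 5
}

#' Per-recording metrics over a set of diagnoses
#'
#' OSA is the positive class. Truth is the OSA status derived from the
#' reference annotations by the same AHI rule the predictions use.
#'
#' @param diagnoses Data frame of [diagnose_recording()] rows (one per
#'   recording), with a logical `osa_flag` column.
#' @param true_osa Logical vector of reference OSA statuses, aligned with
#'   `diagnoses` rows (see [recording_truth()]).
#' @return One-row tibble as from [metrics()], `granularity`
#'   `"per_recording"`.
#' @export
per_recording_metrics <- function(diagnoses, true_osa) {
  stopifnot(is.data.frame(diagnoses), "osa_flag" %in% names(diagnoses))
  if (nrow(diagnoses) != length(true_osa)) {
    abort("one reference OSA status is needed per diagnosed recording.")
  }
  pred <- ifelse(diagnoses$osa_flag, "A", "N")
  truth <- ifelse(as.logical(true_osa), "A", "N")
  metrics(confusion(pred, truth), granularity = "per_recording")
}

#' Format sweep results the way the subband summary table is printed
#'
#' Orders rows as: full band without normalisation first, then the z-scored
#' full band, then the 2-, 4- and 8-band subbands in frequency order.
#' Percentages are rounded half-up to one decimal and per-recording values
#' are parenthesised next to the per-minute ones.
#'
#' @param results A sweep results tibble from [run_sweep()] (numeric
#'   columns `acc`, `spec`, `sen`, `rec_acc`, `rec_spec`, `rec_sen`).
#' @return Tibble with `frequency_band`, `normalized`, and formatted
#'   `acc`, `spec`, `sen` character columns; empty input gives an empty
#'   table.
#' @export
sweep_report <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) {
    return(tibble(frequency_band = character(), normalized = logical(),
                  acc = character(), spec = character(), sen = character()))
  }
  fmt <- function(pm, pr) {
    ifelse(is.na(pm) & is.na(pr), NA_character_,
           sprintf("%.1f (%.1f)", round_half_up(pm, 1), round_half_up(pr, 1)))
  }
  ord <- order(results$n_bands, results$normalized, results$band_index)
  out <- results[ord, ]
  tibble(
    frequency_band = out$label,
    normalized = out$normalized,
    acc = fmt(out$acc, out$rec_acc),
    spec = fmt(out$spec, out$rec_spec),
    sen = fmt(out$sen, out$rec_sen)
  )
}
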
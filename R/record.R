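#' Build a single-lead ECG recording object
#'
#' An `ecg_record` bundles an amplitude trace with its sampling rate,
#' per-minute apnea annotations and (optionally) the identity of the subject
#' the recording came from. Minute `i` (0-based) covers samples
#' `[i * 60 * fs, (i + 1) * 60 * fs)`; a trailing partial minute is dropped,
#' and annotations beyond the usable minutes are discarded with a warning.
#'
#' @param samples Numeric amplitude sequence (mV when read from WFDB files).
#' @param fs Sampling rate in Hz (> 0; database-conformant recordings use 100).
#' @param minute_labels Character vector over `"A"` (apnea) / `"N"` (normal),
#'   one per minute. Must cover at least `floor(length(samples) / (60 * fs))`
#'   minutes.
#' @param record_id Recording identifier, e.g. `"a01"`.
#' @param subject_id Optional subject identifier, e.g. `"p1"`.
#'
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 120, by = 0.01))[1:12000],
#'                   fs = 100, minute_labels = c("N", "A"),
#'                   record_id = "demo")
#' usable_minutes(rec)
#' @export
ecg_record <- function(samples, fs, minute_labels, record_id,
                       subject_id = NULL) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  samples <- as.numeric(samples)
  if (anyNA(samples)) abort("`samples` must not contain missing values.")
  minute_labels <- check_labels(minute_labels)
  usable <- floor(length(samples) / (60 * fs))
  if (length(minute_labels) < usable) {
    abort(sprintf(
      "record %s: %d usable minute(s) of signal but only %d label(s).",
      record_id, usable, length(minute_labels)
    ))
  }
  if (length(minute_labels) > usable) {
    warn(sprintf(
      "record %s: %d label(s) beyond the %d usable minute(s) ignored.",
      record_id, length(minute_labels) - usable, usable
    ))
    minute_labels <- minute_labels[seq_len(usable)]
  }
  structure(
    list(
      record_id = as.character(record_id),
      fs = as.numeric(fs),
      samples = samples,
      minute_labels = minute_labels,
      subject_id = if (is.null(subject_id)) NULL else as.character(subject_id)
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record %s>  fs = %g Hz, %d samples (%.1f min), %d labelled minute(s)\n",
    x$record_id, x$fs, length(x$samples),
    length(x$samples) / (60 * x$fs), length(x$minute_labels)
  ))
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  tab <- table(factor(x$minute_labels, levels = c("N", "A")))
  cat(sprintf("  minutes: %d N, %d A\n", tab[["N"]], tab[["A"]]))
  invisible(x)
}

#' Number of whole labelled minutes in a recording
#'
#' @param record An [ecg_record()].
#' @return Integer count, `floor(length(samples) / (60 * fs))`.
#' @export
usable_minutes <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  as.integer(floor(length(record$samples) / (60 * record$fs)))
}

#' Cut a recording into labelled one-minute segments
#'
#' Segment `i` (0-based `minute_index`) covers samples
#' `[i * 60 * fs, (i + 1) * 60 * fs)` — 6000 samples at 100 Hz — and carries
#' the minute's annotation. A recording shorter than one minute yields an
#' empty table.
#'
#' @param record An [ecg_record()].
#' @return A tibble with columns `record_id`, `minute_index` (0-based),
#'   `label`, and `samples` (list-column of numeric vectors of length
#'   `60 * fs`).
#' @export
segment_record <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  n_seg <- usable_minutes(record)
  len <- as.integer(60 * record$fs)
  if (n_seg == 0L) {
    return(tibble(
      record_id = character(), minute_index = integer(),
      label = character(), samples = list()
    ))
  }
  segs <- lapply(seq_len(n_seg) - 1L, function(i) {
    record$samples[(i * len + 1L):((i + 1L) * len)]
  })
  tibble(
    record_id = record$record_id,
    minute_index = seq_len(n_seg) - 1L,
    label = record$minute_labels[seq_len(n_seg)],
    samples = segs
  )
}

#' z-score normalise an amplitude sequence
#'
#' Rescales a signal to zero mean and unit standard deviation,
#' `z = (x - mu) / sigma`, so that a value one standard deviation above the
#' mean maps to exactly 1.0. The standard deviation is the population one
#' (divide by `N`): the goal is normalisation of a fixed segment, not
#' inference about a larger population. A constant input (`sigma = 0`) is
#' returned as all zeros with a warning, so dead channels do not abort a
#' sweep.
#'
#' @param x Non-empty numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' zscore(c(0, 2))        # -1, 1
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) abort("`x` must be non-empty.")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) {
    warn("constant input: standard deviation is 0, returning all zeros.")
    return(rep(0, length(x)))
  }
  (x - mu) / sigma
}

#' z-score normalise every segment of a segment table
#'
#' Applies [zscore()] independently to each one-minute segment (the unit the
#' classifier consumes); a config switch for per-recording normalisation is
#' available in [prepare_subband_data()].
#'
#' @param segments A segment tibble as returned by [segment_record()].
#' @return The same tibble with the `samples` list-column normalised.
#' @export
zscore_segments <- function(segments) {
  stopifnot(is.data.frame(segments), "samples" %in% names(segments))
  segments$samples <- lapply(segments$samples, zscore)
  segments
}
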
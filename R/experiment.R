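#' Prepare train/test matrices for one subband
#'
#' For each recording: filter the whole recording through the selected band
#' (filtering before segmentation, so one-minute windows carry no per-window
#' filter edge transients), cut into one-minute segments, and optionally
#' z-score each segment. Segments are stacked into matrices ordered by
#' recording id and minute, with row maps retained so per-recording
#' diagnoses can be reassembled from per-minute predictions.
#'
#' @param records Named list of [ecg_record()]s.
#' @param split An `apnea_split` over those recordings.
#' @param bank_id One of `"fb1"`, `"fb2"`, `"fb4"`, `"fb8"`.
#' @param band_index 0-based band index within the bank.
#' @param normalize Apply per-minute z-score normalisation (default TRUE).
#' @param mode Filtering mode, `"causal"` (default) or `"zero_phase"`.
#' @param normalize_scope `"per_minute"` (default) or `"per_recording"`:
#'   whether the z-score statistics come from the one-minute segment or the
#'   whole filtered recording.
#' @return A list with `x_train`, `y_train`, `x_test`, `y_test`,
#'   `train_map`/`test_map` (tibbles `record_id`, `minute_index`), and the
#'   band metadata.
#' @export
prepare_subband_data <- function(records, split, bank_id = "fb1",
                                 band_index = 0, normalize = TRUE,
                                 mode = c("causal", "zero_phase"),
                                 normalize_scope = c("per_minute",
                                                     "per_recording")) {
  mode <- match.arg(mode)
  normalize_scope <- match.arg(normalize_scope)
  stopifnot(inherits(split, "apnea_split"))
  n_bands <- as.integer(sub("^fb", "", bank_id))
  if (!n_bands %in% c(1L, 2L, 4L, 8L)) {
    abort(sprintf("unknown bank id %s.", bank_id))
  }
  ids <- c(split$train_ids, split$test_ids)
  missing <- setdiff(ids, names(records))
  if (length(missing) > 0) {
    abort(sprintf("missing recording(s): %s", paste(missing, collapse = ", ")))
  }
  fs <- records[[ids[1]]]$fs
  bank <- filter_bank(n_bands, fs = fs)
  check_band_index(bank, band_index)

  one_side <- function(side_ids) {
    segs <- purrr::map_dfr(sort(side_ids), function(id) {
      rec <- records[[id]]
      filtered <- apply_filter_bank(rec$samples, bank,
                                    mode = mode)[[band_index + 1L]]
      if (normalize && normalize_scope == "per_recording") {
        filtered <- zscore(filtered)
      }
      frec <- rec
      frec$samples <- filtered
      out <- segment_record(frec)
      if (normalize && normalize_scope == "per_minute") {
        out <- zscore_segments(out)
      }
      out
    })
    list(
      x = do.call(rbind, segs$samples),
      y = segs$label,
      map = segs[c("record_id", "minute_index")]
    )
  }
  tr <- one_side(split$train_ids)
  te <- one_side(split$test_ids)
  list(
    x_train = tr$x, y_train = tr$y, train_map = tr$map,
    x_test = te$x, y_test = te$y, test_map = te$map,
    bank_id = bank_id, band_index = as.integer(band_index),
    label = bank$bands$label[band_index + 1L],
    n_bands = n_bands, normalize = normalize, mode = mode,
    preprocess_hash = hash(list(bank_id, as.integer(band_index),
                                normalize, normalize_scope, mode, fs))
  )
}

#' Run one subband experiment: filter, train, evaluate
#'
#' Trains the classifier on the training side of the split with the
#' repeat-and-select protocol, then evaluates the selected model on the
#' test side: per-minute accuracy/sensitivity/specificity, and
#' per-recording AHI-based OSA diagnoses scored against the AHI rule
#' applied to the reference annotations. Fully deterministic given the
#' seeds in `train_cfg`.
#'
#' @inheritParams prepare_subband_data
#' @param architecture A [cnn_architecture()] whose `input_len` matches
#'   `60 * fs`.
#' @param train_cfg A [train_config()].
#' @param out_dir Optional directory; when given, the training histories,
#'   metrics and reproducibility metadata are written there as CSV/YAML.
#' @return An object of class `subband_result`: `per_minute` and
#'   `per_recording` metric rows, `diagnoses`, the `selection`
#'   ([repeat_and_select()] result) and `metadata`.
#' @export
run_subband <- function(records, split, bank_id, band_index, architecture,
                        train_cfg, normalize = TRUE,
                        mode = c("causal", "zero_phase"), out_dir = NULL) {
  mode <- match.arg(mode)
  data <- prepare_subband_data(records, split, bank_id, band_index,
                               normalize = normalize, mode = mode)
  if (ncol(data$x_train) != architecture$input_len) {
    abort(sprintf(
      "architecture expects input_len %d but segments have %d samples.",
      architecture$input_len, ncol(data$x_train)
    ))
  }
  selection <- repeat_and_select(function(seed) {
    model <- build_cnn(architecture, seed = seed)
    train_cnn(model, data$x_train, data$y_train, data$x_test, data$y_test,
              train_cfg, seed = seed)
  }, train_cfg)

  pred <- predict(selection$best_fit$model, data$x_test, type = "label")
  per_minute <- metrics(confusion(pred, data$y_test))

  by_rec <- split(seq_along(pred), data$test_map$record_id)
  diagnoses <- purrr::map_dfr(names(by_rec), function(id) {
    diagnose_recording(pred[by_rec[[id]]], record_id = id)
  })
  truth <- vapply(names(by_rec), function(id) {
    recording_truth(data$y_test[by_rec[[id]]])
  }, logical(1))
  per_recording <- per_recording_metrics(diagnoses, truth)

  metadata <- list(
    bank_id = bank_id, band_index = as.integer(band_index),
    label = data$label, normalize = normalize, mode = mode,
    split = split$name,
    n_train_minutes = nrow(data$x_train),
    n_test_minutes = nrow(data$x_test),
    architecture = unclass(architecture[c(
      "input_len", "n_feature_blocks", "conv_channels", "kernel_len",
      "pool_size", "dropout", "n_fc_blocks", "fc_width", "n_outputs"
    )]),
    train_config = unclass(train_cfg),
    preprocess_hash = data$preprocess_hash,
    config_hash = hash(list(data$preprocess_hash, unclass(train_cfg),
                            architecture$flatten_width)),
    best_repeat = selection$best_repeat,
    best_epoch = selection$best_epoch
  )
  result <- structure(
    list(per_minute = per_minute, per_recording = per_recording,
         diagnoses = diagnoses, selection = selection,
         metadata = metadata),
    class = "subband_result"
  )
  if (!is.null(out_dir)) write_subband_artifacts(result, out_dir)
  result
}

#' @export
print.subband_result <- function(x, ...) {
  cat(sprintf(
    "<subband_result %s band %d (%s), %s>\n", x$metadata$bank_id,
    x$metadata$band_index, x$metadata$label,
    if (x$metadata$normalize) "z-scored" else "no normalisation"
  ))
  cat(sprintf(
    "  per-minute: Acc %.1f%%  Spec %.1f%%  Sen %.1f%%\n",
    x$per_minute$acc, x$per_minute$spec, x$per_minute$sen
  ))
  cat(sprintf(
    "  per-recording: Acc %.1f%%  Spec %.1f%%  Sen %.1f%%\n",
    x$per_recording$acc, x$per_recording$spec, x$per_recording$sen
  ))
  invisible(x)
}

#' @rdname run_subband
#' @param x A `subband_result`.
#' @param ... Unused.
#' @export
glance.subband_result <- function(x, ...) {
  tibble(
    bank_id = x$metadata$bank_id,
    n_bands = as.integer(sub("^fb", "", x$metadata$bank_id)),
    band_index = x$metadata$band_index,
    label = x$metadata$label,
    normalized = x$metadata$normalize,
    acc = x$per_minute$acc, spec = x$per_minute$spec,
    sen = x$per_minute$sen,
    rec_acc = x$per_recording$acc, rec_spec = x$per_recording$spec,
    rec_sen = x$per_recording$sen,
    best_repeat = x$metadata$best_repeat,
    best_epoch = x$metadata$best_epoch
  )
}

write_subband_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_band%d_%s", result$metadata$bank_id,
                  result$metadata$band_index,
                  if (result$metadata$normalize) "z" else "raw")
  hist <- purrr::map_dfr(seq_along(result$selection$fits), function(r) {
    dplyr::mutate(tidy(result$selection$fits[[r]]), repeat_index = r)
  })
  write.csv(hist, file.path(out_dir, paste0(stem, "_history.csv")),
            row.names = FALSE)
  write.csv(glance(result), file.path(out_dir, paste0(stem, "_metrics.csv")),
            row.names = FALSE)
  yaml::write_yaml(result$metadata,
                   file.path(out_dir, paste0(stem, "_metadata.yaml")))
  invisible(out_dir)
}

#' Sweep the classifier over subbands
#'
#' Runs [run_subband()] for every requested subband (all 15 by default,
#' plus the full 0.5--49.5 Hz band without normalisation, reproducing the
#' published sweep structure: 16 configurations). Each row gets its own
#' deterministically derived seed; a failing row is marked `failed` and the
#' sweep continues.
#'
#' @inheritParams run_subband
#' @param subbands Tibble of subbands to run (columns `bank_id`,
#'   `band_index`), default [subband_table()].
#' @param include_unnormalized_fullband Prepend the fb1 row without
#'   z-score normalisation.
#' @return A tibble of class `apnea_sweep`, one row per configuration, with
#'   per-minute and per-recording metrics; use [sweep_report()] for the
#'   printed layout.
#' @export
run_sweep <- function(records, split, architecture, train_cfg,
                      subbands = subband_table(),
                      include_unnormalized_fullband = TRUE,
                      mode = c("causal", "zero_phase"), out_dir = NULL) {
  mode <- match.arg(mode)
  plan <- tibble(
    bank_id = subbands$bank_id,
    band_index = as.integer(subbands$band_index),
    normalized = TRUE
  )
  if (include_unnormalized_fullband) {
    plan <- dplyr::bind_rows(
      tibble(bank_id = "fb1", band_index = 0L, normalized = FALSE), plan
    )
  }
  rows <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    cfg_i <- train_cfg
    cfg_i$seed <- derive_seed(train_cfg$seed, i)
    res <- tryCatch(
      run_subband(records, split, plan$bank_id[i], plan$band_index[i],
                  architecture, cfg_i, normalize = plan$normalized[i],
                  mode = mode, out_dir = out_dir),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      nb <- as.integer(sub("^fb", "", plan$bank_id[i]))
      return(tibble(
        bank_id = plan$bank_id[i], n_bands = nb,
        band_index = plan$band_index[i],
        label = filter_bank(nb)$bands$label[plan$band_index[i] + 1L],
        normalized = plan$normalized[i],
        acc = NA_real_, spec = NA_real_, sen = NA_real_,
        rec_acc = NA_real_, rec_spec = NA_real_, rec_sen = NA_real_,
        best_repeat = NA_integer_, best_epoch = NA_integer_,
        failed = TRUE, error = conditionMessage(res)
      ))
    }
    dplyr::mutate(glance(res), failed = FALSE, error = NA_character_)
  })
  class(rows) <- c("apnea_sweep", class(rows))
  rows
}
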
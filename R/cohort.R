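#' The PhysioNet Apnea-ECG recording-to-subject map
#'
#' The 70 released recordings (a01--a20, b01--b05, c01--c10 in the original
#' training half; x01--x35 in the original test half) come from only 32
#' distinct subjects: several subjects contributed recordings to both halves,
#' so the original split is subject-dependent. The packaged map lists, for
#' every recording, its subject, which original half it belongs to, and
#' whether the subject's recordings were selected into the subject-independent
#' training set (a subject-level flag: all recordings of a subject share it).
#'
#' The map is validated at load time against the pinned aggregates: 70
#' recordings, 32 subjects, 18 subjects with recordings in both original
#' halves, 23 original-test recordings sharing a subject with the original
#' training half, and 35 recordings flagged for the subject-independent
#' training set.
#'
#' @param path Optional path to an alternative map CSV with columns
#'   `recording_id`, `subject_id`, `original_half`, `independent_train_flag`
#'   (defaults to the packaged map).
#' @return A tibble with one row per recording.
#' @export
cohort_map <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$cohort_map)) return(the$cohort_map)
    path <- system.file("extdata", "apnea_ecg_cohort.csv",
                        package = "apneaband", mustWork = TRUE)
    map <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
    validate_cohort_map(map)
    the$cohort_map <- map
    return(map)
  }
  map <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_cohort_map(map)
  map
}

validate_cohort_map <- function(map) {
  need <- c("recording_id", "subject_id", "original_half",
            "independent_train_flag")
  if (!all(need %in% names(map))) {
    abort(sprintf("cohort map must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (nrow(map) != 70L) abort("cohort map must list exactly 70 recordings.")
  if (anyDuplicated(map$recording_id)) {
    abort("cohort map has duplicated recording ids.")
  }
  if (length(unique(map$subject_id)) != 32L) {
    abort("cohort map must list exactly 32 subjects.")
  }
  if (!all(map$original_half %in% c("train", "test"))) {
    abort("original_half must be 'train' or 'test'.")
  }
  flag_ok <- vapply(split(map$independent_train_flag, map$subject_id),
                    function(f) length(unique(f)) == 1L, logical(1))
  if (!all(flag_ok)) {
    abort("independent_train_flag must be constant within each subject.")
  }
  agg <- cohort_aggregates(map)
  if (agg$shared_subjects != 18L) {
    abort("cohort map: expected 18 subjects with recordings in both halves.")
  }
  if (agg$contaminated_test_recordings != 23L) {
    abort("cohort map: expected 23 contaminated original-test recordings.")
  }
  if (agg$independent_train_recordings != 35L) {
    abort("cohort map: expected 35 subject-independent training recordings.")
  }
  invisible(map)
}

#' Pinned aggregate counts of a cohort map
#'
#' @param map A cohort map tibble, see [cohort_map()].
#' @return One-row tibble: number of recordings, subjects, subjects with
#'   recordings in both original halves, original-test recordings whose
#'   subject also appears in the original training half, and recordings /
#'   subjects selected into the subject-independent training set.
#' @export
cohort_aggregates <- function(map = cohort_map()) {
  halves <- split(map$original_half, map$subject_id)
  shared <- names(halves)[vapply(halves, function(h)
    all(c("train", "test") %in% h), logical(1))]
  test_recs <- map[map$original_half == "test", ]
  tibble(
    recordings = nrow(map),
    subjects = length(unique(map$subject_id)),
    shared_subjects = length(shared),
    contaminated_test_recordings =
      sum(test_recs$subject_id %in% shared),
    independent_train_recordings = sum(map$independent_train_flag),
    independent_train_subjects =
      length(unique(map$subject_id[map$independent_train_flag]))
  )
}

#' Look up the subject a recording belongs to
#'
#' @param recording_id Character vector of recording ids (e.g. `"a02"`).
#' @param map Cohort map tibble.
#' @return Character vector of subject ids.
#' @examples
#' subject_of("a02")   # "p2"
#' @export
subject_of <- function(recording_id, map = cohort_map()) {
  idx <- match(recording_id, map$recording_id)
  if (anyNA(idx)) {
    abort(sprintf("unknown recording id(s): %s",
                  paste(recording_id[is.na(idx)], collapse = ", ")))
  }
  map$subject_id[idx]
}

#' Build the subject-dependent or subject-independent recording split
#'
#' The subject-dependent split is the database's original one: a01--a20,
#' b01--b05, c01--c10 train vs x01--x35 test (35 / 35 recordings), under
#' which 18 subjects have recordings on both sides. The subject-independent
#' split instead trains on all recordings of the flagged subjects (35
#' recordings) and tests on the remainder (35 recordings), so no subject
#' appears on both sides.
#'
#' @param name `"subject_dependent"` or `"subject_independent"`.
#' @param map Cohort map tibble.
#' @return An object of class `apnea_split`: a list with `name`, `train_ids`
#'   and `test_ids`.
#' @export
build_split <- function(name = c("subject_dependent", "subject_independent"),
                        map = cohort_map()) {
  name <- match.arg(name)
  train <- if (name == "subject_dependent") {
    map$recording_id[map$original_half == "train"]
  } else {
    map$recording_id[map$independent_train_flag]
  }
  new_split(name, sort(train), sort(setdiff(map$recording_id, train)))
}

#' Construct a recording split by hand
#'
#' Used for synthetic datasets; [build_split()] covers the packaged cohort.
#'
#' @param name Split label.
#' @param train_ids,test_ids Disjoint character vectors of recording ids.
#' @return An `apnea_split` object.
#' @export
new_split <- function(name, train_ids, test_ids) {
  if (length(intersect(train_ids, test_ids)) > 0) {
    abort("train and test recording sets must be disjoint.")
  }
  structure(list(name = name,
                 train_ids = as.character(train_ids),
                 test_ids = as.character(test_ids)),
            class = "apnea_split")
}

#' @export
print.apnea_split <- function(x, ...) {
  cat(sprintf("<apnea_split %s>  %d train / %d test recordings\n",
              x$name, length(x$train_ids), length(x$test_ids)))
  invisible(x)
}

#' @export
as_tibble.apnea_split <- function(x, ...) {
  tibble(
    recording_id = c(x$train_ids, x$test_ids),
    side = rep(c("train", "test"),
               c(length(x$train_ids), length(x$test_ids)))
  )
}

#' Audit a split for subject leakage between train and test
#'
#' Counts the subjects contributing recordings to both sides, and the test
#' recordings whose subject also appears on the training side. A
#' subject-independent split scores zero on both.
#'
#' @param split An `apnea_split`.
#' @param map A map with columns `recording_id` and `subject_id` (the
#'   packaged cohort map by default; a synthetic manifest works too).
#' @return One-row tibble: `shared_subject_count`,
#'   `contaminated_test_recordings`, plus list-columns `shared_subjects` and
#'   `contaminated_test_ids` with the offenders.
#' @export
leakage_audit <- function(split, map = cohort_map()) {
  stopifnot(inherits(split, "apnea_split"))
  tr_sub <- unique(subject_of(split$train_ids, map))
  te_sub <- subject_of(split$test_ids, map)
  shared <- intersect(tr_sub, unique(te_sub))
  contaminated <- split$test_ids[te_sub %in% shared]
  tibble(
    split = split$name,
    shared_subject_count = length(shared),
    contaminated_test_recordings = length(contaminated),
    shared_subjects = list(sort(shared)),
    contaminated_test_ids = list(sort(contaminated))
  )
}

#' Count normal and apnea minutes on each side of a split
#'
#' @param split An `apnea_split`.
#' @param records Named list of [ecg_record()]s covering every recording in
#'   the split (names are recording ids).
#' @return Tibble with one row per side: `side`, `n_normal`, `n_apnea`,
#'   `total`.
#' @export
event_count_summary <- function(split, records) {
  stopifnot(inherits(split, "apnea_split"))
  ids <- c(split$train_ids, split$test_ids)
  missing <- setdiff(ids, names(records))
  if (length(missing) > 0) {
    abort(sprintf("missing recording(s): %s", paste(missing, collapse = ", ")))
  }
  count_side <- function(side_ids) {
    labs <- unlist(lapply(records[side_ids],
                          function(r) r$minute_labels), use.names = FALSE)
    c(n_normal = sum(labs == "N"), n_apnea = sum(labs == "A"))
  }
  tr <- count_side(split$train_ids)
  te <- count_side(split$test_ids)
  tibble(
    side = c("train", "test"),
    n_normal = c(tr[["n_normal"]], te[["n_normal"]]),
    n_apnea = c(tr[["n_apnea"]], te[["n_apnea"]]),
    total = n_normal + n_apnea
  )
}
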
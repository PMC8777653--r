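test_that("usable minutes follow the floor rule and partial minutes drop", {
  rec <- ecg_record(numeric(12000), fs = 100, minute_labels = c("N", "A"),
                    record_id = "r1")
  expect_equal(usable_minutes(rec), 2L)

  # 12345 samples -> 2 usable minutes, trailing 345 samples dropped
  rec2 <- ecg_record(numeric(12345), fs = 100, minute_labels = c("N", "A"),
                     record_id = "r2")
  expect_equal(usable_minutes(rec2), 2L)
  expect_equal(nrow(segment_record(rec2)), 2L)

  # labels beyond usable minutes are ignored with a warning
  expect_warning(
    rec3 <- ecg_record(numeric(6000), fs = 100,
                       minute_labels = c("N", "A", "A"), record_id = "r3"),
    "ignored"
  )
  expect_equal(rec3$minute_labels, "N")

  # too few labels is a hard error
  expect_error(
    ecg_record(numeric(18000), fs = 100, minute_labels = "N",
               record_id = "r4"),
    "label"
  )
  expect_error(
    ecg_record(numeric(100), fs = 0, minute_labels = character(),
               record_id = "r5"),
    "fs"
  )
  expect_error(
    ecg_record(numeric(6000), fs = 100, minute_labels = "X",
               record_id = "r6"),
    "X"
  )
})

test_that("segmentation partitions the signal and preserves labels in order", {
  rec <- toy_record(minutes = 3, labels = c("N", "N", "A"))
  segs <- segment_record(rec)
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$label, c("N", "N", "A"))
  expect_equal(segs$minute_index, 0:2)
  expect_true(all(lengths(segs$samples) == 6000L))
  # concatenating the segments reproduces the head of the record
  expect_identical(unlist(segs$samples), rec$samples[1:18000])

  # below one minute -> zero segments, not an error
  short <- ecg_record(numeric(5999), fs = 100, minute_labels = character(),
                      record_id = "s")
  expect_equal(nrow(segment_record(short)), 0L)
})

test_that("segment count equals floor(n / (60 fs)) across random lengths", {
  set.seed(7)
  for (i in 1:20) {
    fs <- sample(c(10, 50, 100), 1)
    n <- sample.int(10 * 60 * fs, 1)
    usable <- floor(n / (60 * fs))
    rec <- ecg_record(numeric(n), fs = fs,
                      minute_labels = rep("N", usable), record_id = "x")
    expect_equal(nrow(segment_record(rec)), usable)
  }
})

test_that("columns dialect round-trips samples and labels exactly", {
  rec <- toy_record(minutes = 2, labels = c("N", "A"), seed = 3,
                    record_id = "col01")
  base <- file.path(withr::local_tempdir(), "col01")
  write_ecg_record(rec, base, dialect = "columns")
  back <- read_ecg_record(base, dialect = "columns")
  expect_equal(back$samples, rec$samples)
  expect_identical(back$minute_labels, rec$minute_labels)
  expect_identical(back$record_id, "col01")
  expect_equal(back$fs, 100)
})

test_that("columns dialect rejects missing sidecar, bad fs and bad labels", {
  dir <- withr::local_tempdir()
  base <- file.path(dir, "r")
  writeLines(c("0.1", "0.2"), paste0(base, ".txt"))
  expect_error(read_ecg_record(base, dialect = "columns"), "sidecar")
  yaml::write_yaml(list(fs = -5, labels = "N"), paste0(base, ".yaml"))
  expect_error(read_ecg_record(base, dialect = "columns"), "fs")
  yaml::write_yaml(list(fs = 100, labels = "NQ"), paste0(base, ".yaml"))
  expect_error(read_ecg_record(base, dialect = "columns"), "Q")
})

test_that("WFDB dialect round-trips in formats 16 and 212", {
  rec <- toy_record(minutes = 3, labels = c("N", "A", "A"), seed = 9,
                    record_id = "w01")
  for (fmt in c("16", "212")) {
    base <- file.path(withr::local_tempdir(), "w01")
    write_ecg_record(rec, base, dialect = "wfdb", dat_format = fmt)
    back <- read_ecg_record(base, dialect = "wfdb")
    # quantised to 1/200 mV by the 200 adu/mV gain
    expect_equal(back$samples, rec$samples, tolerance = 1 / 200)
    expect_lt(max(abs(back$samples - rec$samples)), 1 / 200)
    expect_identical(back$minute_labels, rec$minute_labels)
    expect_equal(back$fs, 100)
  }
})

test_that("WFDB reader errors on missing annotations and unknown symbols", {
  rec <- toy_record(minutes = 1, labels = "N", record_id = "w02")
  base <- file.path(withr::local_tempdir(), "w02")
  write_ecg_record(rec, base, dialect = "wfdb")
  file.remove(paste0(base, ".apn"))
  expect_error(read_ecg_record(base, dialect = "wfdb"), "annotation")

  # an annotation stream with a foreign code must be rejected by name
  write_ecg_record(rec, base, dialect = "wfdb")
  words <- c(5L * 1024L + 0L, 0L)            # MIT code 5 (PVC), not A/N
  writeBin(as.raw(rbind(words %% 256L, words %/% 256L)), paste0(base, ".apn"))
  expect_error(read_ecg_record(base, dialect = "wfdb"), "code 5")
})

test_that("zscore meets its contract and handles the degenerate case", {
  expect_equal(zscore(c(-1, 1)), c(-1, 1))   # mu = 0, population sigma = 1
  expect_equal(zscore(c(0, 2)), c(-1, 1))

  set.seed(11)
  y <- rnorm(500, 3, 7)
  zy <- zscore(y)
  expect_equal(mean(zy), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zy^2)), 1, tolerance = 1e-12)
  # a point exactly one SD above the mean maps to 1.0: rep(c(0, 2), k) has
  # mu = 1 and population sigma = 1, so every 2 must map to exactly 1
  anchor <- rep(c(0, 2), 50)
  expect_equal(unique(zscore(anchor)[anchor == 2]), 1.0)

  expect_warning(z0 <- zscore(rep(4, 10)), "constant")
  expect_identical(z0, rep(0, 10))
  expect_error(zscore(numeric(0)), "non-empty")
})

test_that("zscore is idempotent and affine-invariant", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(200, runif(1, -5, 5), runif(1, 0.1, 10))
    z <- zscore(x)
    expect_equal(zscore(z), z, tolerance = 1e-10)
    a <- runif(1, -3, 3)
    while (abs(a) < 0.1) a <- runif(1, -3, 3)
    b <- runif(1, -10, 10)
    expect_equal(zscore(a * x + b), sign(a) * z, tolerance = 1e-8)
  }
})
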
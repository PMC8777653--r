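test_that("confusion counts partition the minutes with A as positive", {
  cc <- confusion(c("A", "A", "N", "N"), c("A", "N", "N", "A"))
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))

  perfect <- confusion(c("A", "N", "A"), c("A", "N", "A"))
  expect_equal(perfect$fp + perfect$fn, 0L)

  all_n <- confusion(rep("N", 5), c("A", "N", "A", "N", "N"))
  expect_equal(all_n$tp, 0L)
  expect_equal(all_n$fp, 0L)

  expect_error(confusion(c("A", "N"), "A"), "length mismatch")
  expect_error(confusion(c("A", "B"), c("A", "N")), "B")
})

test_that("metrics implement the three ratios exactly", {
  m <- metrics(tibble::tibble(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(m$acc, 70)
  expect_equal(m$sen, 60)
  expect_equal(m$spec, 80)
  expect_equal(m$granularity, "per_minute")

  all_right <- metrics(tibble::tibble(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unlist(all_right[c("acc", "sen", "spec")]),
               c(acc = 100, sen = 100, spec = 100))

  # zero denominator -> NA with warning, other metrics still computed
  expect_warning(m2 <- metrics(tibble::tibble(tp = 0, tn = 8, fp = 2, fn = 0)),
                 "sensitivity")
  expect_true(is.na(m2$sen))
  expect_equal(m2$acc, 80)
  expect_equal(m2$spec, 80)
})

test_that("metrics agree with a brute-force recount over random cases", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(2:60, 1)
    pred <- sample(c("A", "N"), n, replace = TRUE)
    truth <- sample(c("A", "N"), n, replace = TRUE)
    cc <- confusion(pred, truth)
    # brute force: recount every minute individually
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (pred[j] == "A" && truth[j] == "A") tp <- tp + 1
      else if (pred[j] == "N" && truth[j] == "N") tn <- tn + 1
      else if (pred[j] == "A") fp <- fp + 1
      else fn <- fn + 1
    }
    expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
                 c(tp = tp, tn = tn, fp = fp, fn = fn),
                 ignore_attr = TRUE)
    if (tp + fn > 0 && tn + fp > 0) {
      m <- metrics(cc)
      expect_equal(m$acc, 100 * (tp + tn) / n)
      expect_equal(m$sen, 100 * tp / (tp + fn))
      expect_equal(m$spec, 100 * tn / (tn + fp))
      # accuracy is the prevalence-weighted mix of sen and spec
      w <- (tp + fn) / n
      expect_equal(m$acc, w * m$sen + (1 - w) * m$spec)
    }
  }
})

test_that("AHI is a rate per hour with the >= 5 OSA rule", {
  d <- diagnose_recording(rep(c("A", "N"), c(30, 330)), "r1")
  expect_equal(d$ahi, 5)
  expect_true(d$osa_flag)                    # boundary counts as OSA

  d0 <- diagnose_recording(rep("N", 100), "r2")
  expect_equal(d0$ahi, 0)
  expect_false(d0$osa_flag)

  d3 <- diagnose_recording(rep(c("A", "N"), c(24, 456)), "r3")
  expect_equal(d3$ahi, 3)
  expect_false(d3$osa_flag)

  expect_error(diagnose_recording(character(), "r4"), "no predicted")

  # monotone: adding an apnea minute never lowers the AHI... per fixed total
  set.seed(43)
  for (i in 1:20) {
    n <- sample(60:600, 1)
    k <- sample(0:(n - 1), 1)
    a1 <- diagnose_recording(rep(c("A", "N"), c(k, n - k)))$ahi
    a2 <- diagnose_recording(rep(c("A", "N"), c(k + 1, n - k - 1)))$ahi
    expect_gte(a2, a1)
  }
})

test_that("per-recording metrics score OSA diagnoses against the AHI rule", {
  expect_true(recording_truth(rep(c("A", "N"), c(30, 330))))
  expect_false(recording_truth(rep("N", 10)))

  # 35 recordings: 25 OSA, 10 non-OSA; 2 OSA missed, 1 non-OSA misflagged
  truth <- rep(c(TRUE, FALSE), c(25, 10))
  pred <- truth
  pred[c(1, 2)] <- FALSE
  pred[26] <- TRUE
  diag <- tibble::tibble(record_id = sprintf("r%02d", 1:35), osa_flag = pred)
  m <- per_recording_metrics(diag, truth)
  expect_equal(m$acc, 100 * 32 / 35)         # 91.4% printed to one decimal
  expect_equal(round(m$acc, 1), 91.4)
  expect_equal(m$granularity, "per_recording")

  all_good <- per_recording_metrics(
    tibble::tibble(record_id = c("a", "b"), osa_flag = c(TRUE, FALSE)),
    c(TRUE, FALSE)
  )
  expect_equal(all_good$acc, 100)
})

test_that("sweep reports order rows canonically and format percentages", {
  results <- tibble::tibble(
    bank_id = c("fb2", "fb1", "fb1", "fb2"),
    n_bands = c(2L, 1L, 1L, 2L),
    band_index = c(1L, 0L, 0L, 0L),
    label = c("25–49.5 Hz", "0.5–49.5 Hz", "0.5–49.5 Hz", "0.5–25 Hz"),
    normalized = c(TRUE, TRUE, FALSE, TRUE),
    acc = c(86.44, 86.71, 86.12, 80.35),
    spec = c(87.7, 89.8, 89.7, 90.9),
    sen = c(84.3, 81.7, 80.1, 63.8),
    rec_acc = c(91.43, 94.3, 82.9, 82.9),
    rec_spec = c(90, 100, 58.3, 70),
    rec_sen = c(92, 91.3, 95.7, 88)
  )
  rep <- sweep_report(results)
  # unnormalised full band first, then z-scored, then fb2 in band order
  expect_equal(rep$normalized, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(rep$frequency_band,
               c("0.5–49.5 Hz", "0.5–49.5 Hz", "0.5–25 Hz", "25–49.5 Hz"))
  expect_equal(rep$acc[1], "86.1 (82.9)")
  expect_equal(rep$acc[3], "80.4 (82.9)")    # half-up rounding of 80.35
  expect_equal(rep$acc[4], "86.4 (91.4)")

  empty <- sweep_report(results[0, ])
  expect_equal(nrow(empty), 0L)
})
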
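test_that("generation is fully determined by the seed", {
  cfg <- synthetic_config(duration_min = 3, seed = 77)
  r1 <- generate_record(cfg, "a")
  r2 <- generate_record(cfg, "a")
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$minute_labels, r2$minute_labels)
  r3 <- generate_record(synthetic_config(duration_min = 3, seed = 78), "a")
  expect_false(identical(r1$samples, r3$samples))
})

test_that("config validation rejects unphysiological settings", {
  expect_error(synthetic_config(cvhr_depth = 1.2), "cvhr_depth")
  expect_error(synthetic_config(p_na = -0.1), "probabilities")
  w <- default_waves()
  w$amp_mv[w$wave == "P"] <- 2               # P above R
  expect_error(synthetic_config(wave_amplitudes = w), "R wave")
  expect_error(synthetic_config(noise_sd = -1), "non-negative")
})

test_that("a clean 1 s rhythm yields 60 +/- 1 R peaks per minute", {
  cfg <- synthetic_config(duration_min = 2, rr_base = 1, rr_jitter_sd = 0,
                          cvhr_depth = 0, noise_sd = 0,
                          baseline_wander_amp = 0, seed = 5)
  rec <- generate_record(cfg)
  x <- rec$samples[1:6000]
  # threshold peak-counting oracle: local maxima above half the R amplitude
  peaks <- which(x > 0.5 & x >= c(x[-1], Inf) & x > c(-Inf, x[-length(x)]))
  expect_true(abs(length(peaks) - 60) <= 1)
})

test_that("label frequencies approach the Markov stationary distribution", {
  cfg <- synthetic_config(duration_min = 600, seed = 15, p_na = 0.05,
                          p_an = 0.08)
  rec <- generate_record(cfg)
  frac_a <- mean(rec$minute_labels == "A")
  expect_equal(frac_a, 0.05 / 0.13, tolerance = 0.25)
})

test_that("spectral content reflects wave morphology", {
  # P/T-only signal: broad low-frequency bumps
  w <- default_waves()
  w_pt <- w
  w_pt$amp_mv[w_pt$wave %in% c("Q", "S")] <- 0
  w_pt$amp_mv[w_pt$wave == "R"] <- 0.5       # keep R > P,T but small & wide
  w_pt$width_s[w_pt$wave == "R"] <- 0.08
  cfg_pt <- synthetic_config(duration_min = 2, wave_amplitudes = w_pt,
                             noise_sd = 0, baseline_wander_amp = 0,
                             seed = 6)
  s_pt <- spectral_summary(generate_record(cfg_pt))
  below_12_5 <- sum(s_pt$energy_fraction[s_pt$high_hz <= 12.5])
  expect_gt(below_12_5 / sum(s_pt$energy_fraction), 0.80)

  # narrow-R-only signal pushes energy above 12.5 Hz
  w_r <- w
  w_r$amp_mv[w_r$wave != "R"] <- 0
  w_r$width_s[w_r$wave == "R"] <- 0.008
  cfg_r <- synthetic_config(duration_min = 2, wave_amplitudes = w_r,
                            noise_sd = 0, baseline_wander_amp = 0, seed = 6)
  s_r <- spectral_summary(generate_record(cfg_r))
  high <- function(s) sum(s$energy_fraction[s$low_hz >= 12.5])
  expect_gt(high(s_r), high(s_pt))

  # zero signal -> all-zero fractions
  zero <- ecg_record(numeric(6000), 100, "N", "z")
  expect_true(all(spectral_summary(zero)$energy_fraction == 0))
})

test_that("datasets carry a manifest that splits without leakage", {
  cfg <- synthetic_config(duration_min = 2, seed = 31)
  ds <- generate_dataset(cfg, n_subjects = 4, records_per_subject = 2)
  expect_length(ds$records, 8L)
  expect_equal(nrow(ds$manifest), 8L)
  expect_length(unique(ds$manifest$subject_id), 4L)

  sp <- manifest_split(ds$manifest)
  aud <- leakage_audit(sp, ds$manifest)
  expect_equal(aud$shared_subject_count, 0L)
  expect_equal(aud$contaminated_test_recordings, 0L)

  expect_error(generate_dataset(cfg, n_subjects = 1), "at least 2")
})

test_that("same-subject recordings resemble each other more than strangers", {
  cfg <- synthetic_config(duration_min = 2, noise_sd = 0.01,
                          cvhr_depth = 0, seed = 55)
  ds <- generate_dataset(cfg, n_subjects = 4, records_per_subject = 2)
  # beat template: average of 120-sample windows around detected R peaks
  template <- function(rec) {
    x <- rec$samples
    peaks <- which(x > 0.5 * max(x) & x >= c(x[-1], Inf) &
                     x > c(-Inf, x[-length(x)]))
    peaks <- peaks[peaks > 60 & peaks < length(x) - 60]
    rowMeans(vapply(peaks, function(p) x[(p - 40):(p + 60)],
                    numeric(101)))
  }
  tpl <- lapply(ds$records, template)
  subj <- setNames(ds$manifest$subject_id, ds$manifest$recording_id)
  ids <- names(tpl)
  within <- c(); cross <- c()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      r <- cor(tpl[[i]], tpl[[j]])
      if (subj[[ids[i]]] == subj[[ids[j]]]) within <- c(within, r)
      else cross <- c(cross, r)
    }
  }
  expect_gt(mean(within), mean(cross))
})

test_that("no energy spike sits at exactly 50 Hz", {
  cfg <- synthetic_config(duration_min = 2, seed = 9)
  rec <- generate_record(cfg)
  x <- rec$samples - mean(rec$samples)
  p <- Mod(fft(x))^2
  n <- length(x)
  freq <- (seq_len(n) - 1) * rec$fs / n
  at_50 <- mean(p[abs(freq - 50) < 0.05])
  neighbourhood <- mean(p[freq > 45 & freq < 49.5])
  expect_lt(at_50, 10 * neighbourhood + 1e-9)
})
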
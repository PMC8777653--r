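#' Configure the synthetic ECG generator
#'
#' The generator emulates the statistical structure the detector relies on:
#' a 100 Hz single-lead ECG built from Gaussian P, Q, R, S and T bumps at
#' fixed intra-beat offsets, per-minute apnea labels drawn from a two-state
#' Markov chain, and — during apnea minutes — cyclic variation of heart rate
#' (CVHR): the RR interval is modulated sinusoidally (bradycardia phases
#' alternating with tachycardia) with amplitude `cvhr_depth * rr_base` and
#' period `cvhr_period`. The modulation ramps in and out over `ramp_s`
#' seconds at minute boundaries so labels do not create instantaneous
#' signal edges. Baseline wander below the 0.5 Hz filter edge and white
#' noise are added on top. An optional amplitude (respiration-like)
#' modulation of the beat waves during apnea minutes is off by default: by
#' default the apnea signature enters only through RR timing.
#'
#' Defaults: 1 s baseline RR (60 bpm), 30 ms RR jitter, depth 0.3, 45 s
#' CVHR period, and Markov transition probabilities (`p_na` = P(N->A) =
#' 0.05, `p_an` = P(A->N) = 0.08) whose stationary apnea fraction (~0.38)
#' matches the event balance of the study database.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_min Recording length in whole minutes.
#' @param rr_base Baseline RR interval, seconds.
#' @param rr_jitter_sd Per-beat white RR jitter SD, seconds.
#' @param cvhr_depth Fraction of `rr_base` by which apnea minutes modulate
#'   RR (0 disables the apnea signature).
#' @param cvhr_period CVHR modulation period, seconds.
#' @param wave_amplitudes Data frame with columns `wave`, `offset_s`,
#'   `width_s`, `amp_mv` describing the five Gaussian bumps.
#' @param baseline_wander_amp,baseline_wander_freq Baseline wander sinusoid
#'   amplitude (mV) and frequency (Hz, below 0.5).
#' @param noise_sd White noise SD, mV.
#' @param p_na,p_an Markov transition probabilities between minute states.
#' @param amp_modulation Amplitude-modulation depth during apnea minutes
#'   (0 = off).
#' @param ramp_s Modulation ramp at minute boundaries, seconds.
#' @param seed Integer seed; generation is fully determined by it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 100, duration_min = 60, rr_base = 1.0,
                             rr_jitter_sd = 0.03, cvhr_depth = 0.3,
                             cvhr_period = 45,
                             wave_amplitudes = default_waves(),
                             baseline_wander_amp = 0.05,
                             baseline_wander_freq = 0.25,
                             noise_sd = 0.02,
                             p_na = 0.05, p_an = 0.08,
                             amp_modulation = 0, ramp_s = 5, seed = 1) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(duration_min, "duration_min", positive = TRUE)
  stopifnot_scalar_number(rr_base, "rr_base", positive = TRUE)
  stopifnot_scalar_number(cvhr_period, "cvhr_period", positive = TRUE)
  if (cvhr_depth < 0 || cvhr_depth >= 1) {
    abort("`cvhr_depth` must be in [0, 1).")
  }
  if (p_na < 0 || p_na > 1 || p_an < 0 || p_an > 1) {
    abort("transition probabilities must lie in [0, 1].")
  }
  if (rr_jitter_sd < 0 || noise_sd < 0 || baseline_wander_amp < 0) {
    abort("noise amplitudes must be non-negative.")
  }
  w <- as_tibble(wave_amplitudes)
  need <- c("wave", "offset_s", "width_s", "amp_mv")
  if (!all(need %in% names(w))) {
    abort(sprintf("`wave_amplitudes` needs columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (any(w$width_s <= 0)) abort("wave widths must be positive.")
  r_amp <- abs(w$amp_mv[w$wave == "R"])
  pt_amp <- abs(w$amp_mv[w$wave %in% c("P", "T")])
  if (length(r_amp) == 1 && length(pt_amp) > 0 && any(pt_amp >= r_amp)) {
    abort("the R wave must be larger than the P and T waves.")
  }
  structure(
    list(fs = fs, duration_min = as.integer(duration_min),
         rr_base = rr_base, rr_jitter_sd = rr_jitter_sd,
         cvhr_depth = cvhr_depth, cvhr_period = cvhr_period,
         wave_amplitudes = w,
         baseline_wander_amp = baseline_wander_amp,
         baseline_wander_freq = baseline_wander_freq,
         noise_sd = noise_sd, p_na = p_na, p_an = p_an,
         amp_modulation = amp_modulation, ramp_s = ramp_s,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_waves <- function() {
  tibble(
    wave = c("P", "Q", "R", "S", "T"),
    offset_s = c(-0.20, -0.04, 0.00, 0.04, 0.30),
    width_s = c(0.040, 0.012, 0.012, 0.012, 0.070),
    amp_mv = c(0.12, -0.15, 1.00, -0.20, 0.30)
  )
}

# smoothed apnea indicator at time t (ramped over cfg$ramp_s at boundaries)
apnea_weight <- function(t, labels_A, ramp_s) {
  i <- pmin(floor(t / 60), length(labels_A) - 1L)
  frac <- t - 60 * i
  cur <- labels_A[i + 1L]
  prev <- labels_A[pmax(i, 1L)]              # minute 0 has no predecessor
  ifelse(frac < ramp_s & ramp_s > 0,
         prev + (cur - prev) * frac / ramp_s, cur)
}

#' Generate one labelled synthetic ECG recording
#'
#' See [synthetic_config()] for the generative model. The same config and
#' seed always reproduce identical samples and labels.
#'
#' @param cfg A [synthetic_config()].
#' @param record_id,subject_id Identifiers carried into the record.
#' @return An [ecg_record()] (amplitudes in mV).
#' @examples
#' rec <- generate_record(synthetic_config(duration_min = 3, seed = 7))
#' rec
#' @export
generate_record <- function(cfg, record_id = "synth01", subject_id = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n_min <- cfg$duration_min
    # minute labels from the 2-state chain, started at its stationary law
    pi_a <- if (cfg$p_na + cfg$p_an > 0) {
      cfg$p_na / (cfg$p_na + cfg$p_an)
    } else 0
    labels <- character(n_min)
    state <- if (runif(1) < pi_a) "A" else "N"
    for (i in seq_len(n_min)) {
      labels[i] <- state
      p_switch <- if (state == "N") cfg$p_na else cfg$p_an
      if (runif(1) < p_switch) state <- if (state == "N") "A" else "N"
    }
    labels_A <- as.numeric(labels == "A")

    dur <- 60 * n_min
    # beat times from the RR process conditioned on the labels
    beats <- numeric(ceiling(dur / (0.4 * cfg$rr_base)) + 2L)
    nb <- 0L
    t <- 0.3
    while (t < dur) {
      nb <- nb + 1L
      beats[nb] <- t
      w <- apnea_weight(t, labels_A, cfg$ramp_s)
      rr <- cfg$rr_base + rnorm(1, 0, cfg$rr_jitter_sd) +
        cfg$rr_base * cfg$cvhr_depth * w *
          sin(2 * pi * t / cfg$cvhr_period)
      t <- t + min(max(rr, 0.4 * cfg$rr_base), 2 * cfg$rr_base)
    }
    beats <- beats[seq_len(nb)]

    n <- as.integer(dur * cfg$fs)
    tt <- (seq_len(n) - 1L) / cfg$fs
    x <- numeric(n)
    wv <- cfg$wave_amplitudes
    for (b in beats) {
      amp_scale <- 1
      if (cfg$amp_modulation > 0) {
        w <- apnea_weight(b, labels_A, cfg$ramp_s)
        amp_scale <- 1 + cfg$amp_modulation * w *
          sin(2 * pi * b / cfg$cvhr_period)
      }
      for (j in seq_len(nrow(wv))) {
        centre <- b + wv$offset_s[j]
        width <- wv$width_s[j]
        lo <- max(1L, as.integer(floor((centre - 4 * width) * cfg$fs)) + 1L)
        hi <- min(n, as.integer(ceiling((centre + 4 * width) * cfg$fs)) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        x[idx] <- x[idx] + amp_scale * wv$amp_mv[j] *
          exp(-0.5 * ((tt[idx] - centre) / width)^2)
      }
    }
    if (cfg$baseline_wander_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      x <- x + cfg$baseline_wander_amp *
        sin(2 * pi * cfg$baseline_wander_freq * tt + phase)
    }
    if (cfg$noise_sd > 0) x <- x + rnorm(n, 0, cfg$noise_sd)
    ecg_record(x, cfg$fs, labels, record_id = record_id,
               subject_id = subject_id)
  })
}

#' Generate a multi-subject synthetic dataset with a manifest
#'
#' Each subject gets small deterministic perturbations of the baseline RR
#' interval and wave amplitudes (derived from the master seed), so records
#' of the same subject resemble each other more than records of different
#' subjects — the property that makes subject-dependent splits leak. The
#' manifest maps recordings to subjects and plugs directly into
#' [leakage_audit()] and [new_split()].
#'
#' @param cfg A [synthetic_config()] used as the population baseline.
#' @param n_subjects Number of subjects (>= 2 for split testing).
#' @param records_per_subject Recordings per subject.
#' @return A list with `records` (named list of [ecg_record()]s) and
#'   `manifest` (tibble `recording_id`, `subject_id`).
#' @export
generate_dataset <- function(cfg, n_subjects, records_per_subject = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  records <- list()
  manifest <- tibble(recording_id = character(), subject_id = character())
  for (s in seq_len(n_subjects)) {
    subj <- sprintf("sub%02d", s)
    pert <- with_seed(derive_seed(cfg$seed, s), {
      list(rr_mult = exp(rnorm(1, 0, 0.08)),
           amp_mult = exp(rnorm(1, 0, 0.12)),
           t_mult = exp(rnorm(1, 0, 0.10)))
    })
    for (r in seq_len(records_per_subject)) {
      rid <- sprintf("s%02dr%02d", s, r)
      rcfg <- cfg
      rcfg$rr_base <- cfg$rr_base * pert$rr_mult
      rcfg$wave_amplitudes$amp_mv <- cfg$wave_amplitudes$amp_mv *
        pert$amp_mult
      rcfg$wave_amplitudes$amp_mv[cfg$wave_amplitudes$wave == "T"] <-
        cfg$wave_amplitudes$amp_mv[cfg$wave_amplitudes$wave == "T"] *
          pert$amp_mult * pert$t_mult
      rcfg$seed <- derive_seed(cfg$seed, s, r)
      records[[rid]] <- generate_record(rcfg, record_id = rid,
                                        subject_id = subj)
      manifest <- dplyr::bind_rows(
        manifest, tibble(recording_id = rid, subject_id = subj)
      )
    }
  }
  list(records = records, manifest = manifest)
}

#' Subject-disjoint split of a synthetic manifest
#'
#' @param manifest Tibble with `recording_id` and `subject_id`.
#' @param train_subjects Character vector of subjects whose recordings form
#'   the training side (default: the first half of the subjects).
#' @return An `apnea_split`.
#' @export
manifest_split <- function(manifest,
                           train_subjects = NULL) {
  subs <- unique(manifest$subject_id)
  if (is.null(train_subjects)) {
    train_subjects <- subs[seq_len(length(subs) %/% 2)]
  }
  tr <- manifest$recording_id[manifest$subject_id %in% train_subjects]
  te <- setdiff(manifest$recording_id, tr)
  new_split("subject_independent", tr, te)
}

#' Energy fractions of a recording over the eight-band decomposition
#'
#' Periodogram-based summary of where a recording's energy lives: the
#' fraction of total signal energy (after mean removal) falling in each of
#' the eight 0.5--49.5 Hz bands. Fractions sum to at most 1; energy outside
#' 0.5--49.5 Hz accounts for the remainder. A zero signal reports all-zero
#' fractions.
#'
#' @param record An [ecg_record()].
#' @return Tibble with `label`, `low_hz`, `high_hz`, `energy_fraction`.
#' @export
spectral_summary <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples - mean(record$samples)
  n <- length(x)
  p <- Mod(fft(x))^2
  freq <- (seq_len(n) - 1L) * record$fs / n
  half <- freq <= record$fs / 2
  p <- p[half]
  freq <- freq[half]
  total <- sum(p)
  bands <- filter_bank(8, fs = record$fs)$bands
  frac <- vapply(seq_len(nrow(bands)), function(i) {
    inb <- freq >= bands$low_hz[i] & freq < bands$high_hz[i]
    if (total == 0) 0 else sum(p[inb]) / total
  }, numeric(1))
  tibble(label = bands$label, low_hz = bands$low_hz,
         high_hz = bands$high_hz, energy_fraction = frac)
}
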
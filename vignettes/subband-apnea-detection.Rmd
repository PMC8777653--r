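---
title: "Subband decomposition and CNN-based sleep apnea detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subband decomposition and CNN-based sleep apnea detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

Obstructive sleep apnea (OSA) leaves a readable trace in a single-lead ECG:
apnea episodes drive a cyclic variation of heart rate (CVHR) — bradycardia
during the event, abrupt tachycardia at its cessation. A detector can
therefore classify each minute of ECG as apnea (`A`) or normal (`N`)
without airflow or oximetry channels, and summarise a whole night by the
apnea–hypopnea index (AHI), approximated here as predicted apnea minutes
per hour; a recording with AHI ≥ 5 is flagged as OSA.

`apneaband` implements that pipeline and, around it, the question of *which
frequency band of the ECG carries the signal*. The full 0.5–49.5 Hz band is
tiled by equal-width fourth-order Butterworth bandpass banks of 1, 2, 4 and
8 filters — 15 subbands in all. Each subband, z-score normalised per
minute, feeds its own one-dimensional convolutional network; per-minute and
per-recording metrics are then compared across subbands. The mid-high
bands, which suppress the large, slow P and T waves while retaining QRS
timing, are the interesting ones: with low-frequency morphology removed,
what remains is closer to a pure RR-interval (beat timing) signal.

The pipeline, in the package's vocabulary:

```{r}
library(apneaband)

cfg   <- synthetic_config(duration_min = 500, cvhr_depth = 0.3, seed = 1)
ds    <- generate_dataset(cfg, n_subjects = 8)
split <- manifest_split(ds$manifest)       # subject-disjoint by construction

arch  <- cnn_architecture()                # the full-scale network
tcfg  <- train_config(epochs = 50, repeats = 5, seed = 1)
res   <- run_subband(ds$records, split, "fb8", 5, arch, tcfg)
```

## Filter-bank design

Bands tile `[0.5, 49.5]` Hz contiguously with interior edges at multiples
of `50/n_bands` Hz; the outer edges are pulled in from 0 and 50 Hz to
0.5/49.5 Hz so baseline wander and mains-adjacent interference are always
rejected (the outer bands are 0.25–0.5 Hz narrower than nominal).
Coefficients come from `signal::butter(4, c(low, high)/(fs/2), "pass")` —
the MATLAB-style convention in which a fourth-order prototype yields an
eighth-degree digital bandpass via the bilinear transform. Design is
deterministic; the test suite asserts pole radii < 1 for every band and a
−3 dB (1/√2) response at every printed corner against an independent
impulse-response/FFT oracle.

Two application axes are deliberately configurable because the method
itself does not fix them:

* **Direction** — `mode = "causal"` (default) is a single forward pass;
  `mode = "zero_phase"` runs forward–backward (`signal::filtfilt`) at the
  cost of non-causality. The choice is recorded in experiment metadata.
* **Scope** — recordings are filtered *whole* and then segmented (default),
  so no per-minute filter edge transients enter the training data. The
  z-score scope is likewise a switch (`normalize_scope`), defaulting to
  per-minute because the classifier's input unit is the one-minute segment.

## Normalisation

`zscore()` maps a segment to zero mean and unit *population* standard
deviation — a normalisation target, not an inference problem, so the `N`
divisor is used and a value exactly one SD above the mean maps to exactly
1.0. A constant segment (σ = 0) returns all zeros with a warning rather
than an error, so a dead channel cannot abort a 16-configuration sweep.

## The classifier

The network is a fixed 1D CNN: ten identical feature-extraction blocks
(convolution with 45 feature maps → batch normalisation → ReLU → max-pool
of size 2 → 50 % dropout), a flatten, four identical classification blocks
(dense 512 → batch normalisation → ReLU → dropout), and a dense 2-unit
softmax head. With floor-semantics pooling the 6000-sample input shrinks
6000 → 3000 → … → 5, giving a flatten width of 5 × 45 = 225. Weights are
He-normal initialised; training is minibatch Adam on cross-entropy.

Kernel length, stride, padding, learning rate and batch size are not fixed
by the method; this implementation defaults to kernel 15, stride 1,
same-padding, learning rate 10⁻³ and batch 128, all explicit in
`cnn_architecture()` / `train_config()` and all recorded in run metadata.
Max-pooling ties route to the earlier sample; odd pooled lengths drop the
trailing element.

The engine is implemented in R directly on BLAS matrix operations:
convolutions are im2col gathers followed by a single matrix product, and a
batch activation lives in a `(batch × length) × channels` matrix. Analytic
gradients for every layer — including spatial batch normalisation — are
verified against central finite differences in the test suite (the only
systematic deviation is the convolution bias feeding a batch-norm layer,
whose true gradient is exactly zero because the normalisation absorbs the
shift). Evaluation mode (running statistics, dropout off) is deterministic
given fixed weights; all RNG streams (init, shuffling, dropout) derive
from explicit seeds, so whole experiments replay exactly.

**Selection protocol.** A run trains for a fixed number of epochs and
records per-epoch training accuracy (running average over minibatches, the
usual minibatch-training convention) and test accuracy (a full evaluation
pass); the protocol repeats the run several times with different seeds
(`seed + repeat index`) and keeps the weights of the (repeat, epoch) with
the highest *test* accuracy. This selection peeks at the test set; it is
reproduced deliberately because it is the protocol under study. For an
honest generalisation estimate, pass a validation set as the test
arguments of `train_cnn()` and evaluate the returned model on a third,
untouched set.

## Cohort splits and leakage

The packaged map (`cohort_map()`) encodes the recording→subject table of
the 70-recording, 32-subject PhysioNet Apnea-ECG cohort verbatim,
validated at load time against its pinned aggregates (70 recordings, 32
subjects, 18 subjects spanning both original halves, 23 contaminated
original-test recordings, 35 subject-independent training recordings). One
discrepancy is documented rather than silently repaired: the printed
subject-independent flags cover **17** subjects owning exactly 35
recordings, while the accompanying prose says 16 subjects; the marks are
shipped as printed because the 35/35 recording split is what the analysis
depends on. No re-derivation of the subject matching (by age/sex/height/
weight metadata) is attempted: the table is data, not an algorithm.

`leakage_audit()` quantifies why subject-dependent evaluation overstates
accuracy: 18 shared subjects, 23 of 35 test recordings with a same-subject
counterpart in training. The subject-independent split audits to zero by
construction, under any permutation of the map.

## The synthetic generator

`generate_record()` emulates exactly the structure the detector exploits,
with full analytic control:

* minute labels from a two-state Markov chain (defaults `P(N→A)` = 0.05,
  `P(A→N)` = 0.08, stationary apnea fraction ≈ 0.38, matching the event
  balance of the real cohort; mean apnea bout ≈ 12 minutes);
* beat times from an RR process: baseline 1.0 s, white jitter (SD 30 ms),
  and during apnea minutes a sinusoidal CVHR modulation of amplitude
  `cvhr_depth × rr_base` (default depth 0.3) and period 45 s, ramped over
  5 s at minute boundaries so labels never create instantaneous edges;
* each beat rendered as five Gaussian bumps (P, Q, R, S, T) at fixed
  intra-beat offsets — a standard synthetic-ECG simplification chosen over
  a dynamical-system model because it makes the frequency content of each
  wave analytically controllable;
* baseline wander below the 0.5 Hz edge plus white noise;
* per-subject perturbations of RR baseline and wave amplitudes (derived
  deterministically from the master seed), so same-subject recordings
  resemble each other more than cross-subject ones — the property that
  makes subject-dependent splits leak.

What it does **not** model: hypopnea as distinct from apnea, sleep-stage
structure, electrode artefacts, ectopic beats, or ECG-derived respiration
amplitude modulation (available behind `amp_modulation`, off by default so
the apnea signature enters only through beat timing). Passing the
synthetic end-to-end test therefore shows the pipeline can recover a
CVHR-style timing signature under controlled conditions; it does not
certify clinical accuracy on real recordings.

## Problem sizes and statistical checks

The packaged experiments run at desk scale, chosen once:

* End-to-end check: 8 synthetic subjects × 500 minutes (within the real
  recordings' 401–587 min range), subject-disjoint 2000/2000 train/test
  minutes, the 25–49.5 Hz band (the QRS-timing band — the setting in which
  beat-interval structure is least obscured by P/T morphology), and a
  reduced network: 5 feature blocks × 8 channels, kernel 9, one dense
  block of 32, dropout 0.2 (lighter than the full model's 0.5, which is
  calibrated to 45-channel capacity), 6 epochs, 1 repeat, batch 64,
  learning rate 2·10⁻³. The receptive field of five pooled blocks
  (~2.5 s) spans adjacent beats, which is what RR-interval sensing needs;
  a shallower stack sees less than one beat pair and cannot learn the
  signature. The trained detector must beat the test-set majority-class
  fraction by a one-sided exact binomial test at α = 0.01 — the majority
  baseline, not 50 %, because the label marginal is imbalanced and
  "always N" is the trivial competitor.
* Null check: the same pipeline with `cvhr_depth = 0` must *not* beat the
  majority baseline, tested at α = 0.001. The stricter level allows for
  the mild upward bias of best-over-epochs selection on a finite test set;
  it guards against gross leakage rather than sharpening the null.
* Determinism: a reduced sweep (full band raw + z-scored fb2 bands, tiny
  network) rerun under the same master seed must reproduce its results
  table byte-identically when serialised.

Reproducing the published full-scale sweep (50 epochs × 5 repeats × 16
configurations on the real database) is an external workflow: it requires
downloading the PhysioNet recordings and substantial compute. The WFDB
reader, the packaged cohort splits and the full-scale
`cnn_architecture()` defaults exist precisely so that workflow is a
data-path change, not a code change.

## Known limitations

* The CNN engine is single-threaded R on BLAS; it is sized for the
  package's experiments, not for GPU-scale training.
* The WFDB dialect covers headers, signal formats 16/212 and apnea
  annotation streams (MIT codes for `N` and `A`, SKIP escapes, AUX
  skipping); it is not a general WFDB implementation.
* Per-recording ground truth for the real cohort is derived by applying
  the same AHI ≥ 5 rule to the reference annotations — symmetric and
  commensurate with the predictions, but a package convention, since the
  source protocol for per-recording truth is not specified.
* The synthetic generator's CVHR parameters are chosen for testability,
  not fitted to any patient population.
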
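#' Design an equal-width Butterworth bandpass filter bank
#'
#' Tiles the 0.5--49.5 Hz band with `n_bands` contiguous equal-width
#' fourth-order Butterworth bandpass filters at sampling rate `fs` (100 Hz
#' for database-conformant signals). Interior band edges sit at multiples of
#' `fs/2 / n_bands` (25, 12.5 or 6.25 Hz at 100 Hz); the outer edges are
#' pulled in to 0.5 and 49.5 Hz so baseline drift and near-Nyquist
#' interference are always rejected, making the two outer bands slightly
#' narrower than nominal. Digital coefficients come from the bilinear
#' transform ([signal::butter()]), following the MATLAB convention in which
#' a fourth-order bandpass prototype yields an eighth-degree digital filter;
#' the design is deterministic.
#'
#' @param n_bands Number of bands: 1, 2, 4 or 8.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth prototype order (default 4).
#' @return An object of class `filter_bank`: band edges, labels and the
#'   designed coefficients.
#' @examples
#' fb8 <- filter_bank(8)
#' tidy(fb8)
#' @export
filter_bank <- function(n_bands, fs = 100, order = 4) {
  if (!is_scalar_number(n_bands) || !n_bands %in% c(1, 2, 4, 8)) {
    abort("`n_bands` must be one of 1, 2, 4, 8.")
  }
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(order, "order", positive = TRUE)
  nominal <- (fs / 2) / n_bands
  low <- (seq_len(n_bands) - 1) * nominal
  high <- seq_len(n_bands) * nominal
  low[1] <- 0.5 * fs / 100                     # 0.5 Hz at fs = 100
  high[n_bands] <- (fs / 2) - 0.5 * fs / 100   # 49.5 Hz at fs = 100
  bands <- tibble(
    band_index = seq_len(n_bands) - 1L,
    low_hz = low,
    high_hz = high,
    label = band_label(low, high)
  )
  filters <- lapply(seq_len(n_bands), function(i) {
    signal::butter(order, c(low[i], high[i]) / (fs / 2), type = "pass")
  })
  structure(
    list(n_bands = as.integer(n_bands), order = as.integer(order),
         fs = as.numeric(fs), bands = bands, filters = filters),
    class = "filter_bank"
  )
}

band_label <- function(low, high) {
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.2f", x))
  paste0(fmt(low), "–", fmt(high), " Hz")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf(
    "<filter_bank fb%d>  order-%d Butterworth bandpass, fs = %g Hz\n",
    x$n_bands, x$order, x$fs
  ))
  cat(" ", paste(x$bands$label, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname filter_bank
#' @param x A `filter_bank`.
#' @param ... Unused.
#' @export
tidy.filter_bank <- function(x, ...) {
  dplyr::mutate(x$bands, bank_id = paste0("fb", x$n_bands), .before = 1)
}

#' Magnitude response of one band of a filter bank
#'
#' Evaluates `|H(f)|` of the designed digital bandpass on the unit circle.
#' By the Butterworth corner property the response is 1/sqrt(2) (-3 dB) at
#' each design edge.
#'
#' @param bank A [filter_bank()].
#' @param band_index 0-based band index.
#' @param freqs Frequencies in Hz, each in `(0, fs/2)`.
#' @return Numeric vector of magnitudes.
#' @export
magnitude_response <- function(bank, band_index, freqs) {
  stopifnot(inherits(bank, "filter_bank"))
  check_band_index(bank, band_index)
  freqs <- as.numeric(freqs)
  if (any(freqs >= bank$fs / 2) || any(freqs < 0)) {
    abort(sprintf("frequencies must lie in [0, %g) Hz (below Nyquist).",
                  bank$fs / 2))
  }
  flt <- bank$filters[[band_index + 1L]]
  z <- exp(-1i * 2 * pi * freqs / bank$fs)
  num <- outer(z, seq_along(flt$b) - 1, `^`) %*% flt$b
  den <- outer(z, seq_along(flt$a) - 1, `^`) %*% flt$a
  as.numeric(Mod(num / den))
}

check_band_index <- function(bank, band_index) {
  if (!is_scalar_number(band_index) || band_index < 0 ||
      band_index >= bank$n_bands || band_index != round(band_index)) {
    abort(sprintf("`band_index` must be an integer in [0, %d].",
                  bank$n_bands - 1L))
  }
}

#' Magnitude-response table of a whole filter bank
#'
#' Convenience wrapper around [magnitude_response()] producing a tidy table
#' for plotting or CSV export.
#'
#' @param bank A [filter_bank()].
#' @param freqs Frequencies in Hz (default: a fine grid below Nyquist).
#' @return Tibble with `band_index`, `label`, `freq_hz`, `magnitude`.
#' @export
filter_bank_response <- function(bank,
                                 freqs = seq(0.01, bank$fs / 2 - 0.01,
                                             length.out = 512)) {
  stopifnot(inherits(bank, "filter_bank"))
  purrr::map_dfr(seq_len(bank$n_bands) - 1L, function(i) {
    tibble(
      band_index = i,
      label = bank$bands$label[i + 1L],
      freq_hz = freqs,
      magnitude = magnitude_response(bank, i, freqs)
    )
  })
}

#' Decompose a signal into its subband components
#'
#' Runs every band of the bank over the signal. The default is a causal
#' single-pass filter; `mode = "zero_phase"` uses forward-backward filtering
#' ([signal::filtfilt()]), which needs at least `3 * (2 * order + 1)` samples
#' of input for its edge-transient handling.
#'
#' @param x Numeric signal.
#' @param bank A [filter_bank()].
#' @param mode `"causal"` (default) or `"zero_phase"`.
#' @return Named list (by band label) of filtered signals, each the length
#'   of `x`.
#' @export
apply_filter_bank <- function(x, bank, mode = c("causal", "zero_phase")) {
  stopifnot(inherits(bank, "filter_bank"))
  mode <- match.arg(mode)
  x <- as.numeric(x)
  if (mode == "zero_phase") {
    min_len <- 3L * (length(bank$filters[[1]]$a) - 1L) + 1L
    if (length(x) < min_len) {
      abort(sprintf(
        "zero-phase filtering needs at least %d samples (got %d).",
        min_len, length(x)
      ))
    }
  }
  out <- lapply(bank$filters, function(flt) {
    if (mode == "causal") {
      as.numeric(signal::filter(flt, x))
    } else {
      as.numeric(signal::filtfilt(flt, x))
    }
  })
  names(out) <- bank$bands$label
  out
}

#' Enumerate the 15 subband configurations
#'
#' The four banks (1, 2, 4 and 8 bands over 0.5--49.5 Hz) define 15 distinct
#' subbands in all; each one, paired with its own classifier, is an
#' independent apnea detector whose contribution can be compared in a sweep.
#'
#' @param fs Sampling rate in Hz.
#' @return Tibble with 15 rows: `bank_id`, `n_bands`, `band_index`,
#'   `low_hz`, `high_hz`, `label`.
#' @export
subband_table <- function(fs = 100) {
  purrr::map_dfr(c(1L, 2L, 4L, 8L), function(nb) {
    fb <- filter_bank(nb, fs = fs)
    dplyr::mutate(fb$bands,
                  bank_id = paste0("fb", nb), n_bands = nb, .before = 1)
  })
}

#' Poles of every band of a filter bank
#'
#' Exposed for stability checks: every designed filter must have all poles
#' strictly inside the unit circle.
#'
#' @param bank A [filter_bank()].
#' @return List of complex pole vectors, one per band.
#' @export
filter_bank_poles <- function(bank) {
  stopifnot(inherits(bank, "filter_bank"))
  lapply(bank$filters, function(flt) polyroot(rev(flt$a)))
}
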
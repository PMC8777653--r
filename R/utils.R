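# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- (as.numeric(seed) + sum(as.numeric(offs) * 10007)) %% 2147483647
  as.integer(s)
}

# round-half-up to `digits` decimals (display convention for percentages);
# the epsilon absorbs binary representation error (e.g. 80.35 * 10 is
# fractionally below 803.5)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(abs(x) * p + 0.5 + 1e-9) / p * sign(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

check_labels <- function(labels, arg = "minute_labels") {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("A", "N"))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains unknown label symbol(s): %s (only \"A\" and \"N\" are allowed).",
      arg, paste(dQuote(bad, q = FALSE), collapse = ", ")
    ))
  }
  labels
}
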
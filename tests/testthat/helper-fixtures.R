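# shared fixtures, all generated in code

# deterministic pseudo-ECG-ish trace (not physiological; cheap)
toy_samples <- function(n, fs = 100, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    tt <- (seq_len(n) - 1) / fs
    sin(2 * pi * 1.1 * tt) + 0.3 * sin(2 * pi * 17 * tt) + rnorm(n, 0, 0.1)
  })
}

toy_record <- function(minutes = 2, fs = 100, labels = NULL, seed = 1,
                       record_id = "toy") {
  labels <- labels %||% rep(c("N", "A"), length.out = minutes)
  ecg_record(toy_samples(minutes * 60 * fs, fs, seed), fs, labels, record_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny architecture/config used wherever a real training run is not the point
tiny_arch <- function(len = 256) {
  cnn_architecture(input_len = len, n_feature_blocks = 2, conv_channels = 4,
                   kernel_len = 5, n_fc_blocks = 1, fc_width = 8)
}
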
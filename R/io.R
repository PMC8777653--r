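#' Read an ECG recording with per-minute apnea annotations
#'
#' Two on-disk dialects are supported.
#'
#' * `"wfdb"`: a PhysioNet-style record made of a header (`<base>.hea`), a
#'   signal file (`<base>.dat`, format 212 or 16) and a binary annotation
#'   file (`<base>.apn`) holding one `A`/`N` symbol per minute in the MIT
#'   annotation format. Gain/baseline fields in the header are honoured
#'   (amplitudes are returned in mV); a missing gain falls back to the
#'   conventional 200 adu/mV.
#' * `"columns"`: a plain-text amplitude file (`<base>.txt`, one sample per
#'   line) with a YAML sidecar (`<base>.yaml`) carrying `fs` and a label
#'   string such as `"NNAAN"`.
#'
#' @param path Base path of the record (extensions are added per dialect;
#'   a `.hea`/`.txt` path is accepted and stripped).
#' @param dialect `"wfdb"` or `"columns"`.
#' @return An [ecg_record()].
#' @seealso [write_ecg_record()]
#' @export
read_ecg_record <- function(path, dialect = c("wfdb", "columns")) {
  dialect <- match.arg(dialect)
  base <- sub("\\.(hea|dat|apn|txt|yaml)$", "", path)
  switch(dialect,
    wfdb = read_wfdb_record(base),
    columns = read_columns_record(base)
  )
}

#' Write an ECG recording to disk
#'
#' Inverse of [read_ecg_record()]; see that help page for the two dialects.
#' WFDB signal files can be written in format 16 (16-bit little-endian) or
#' format 212 (packed 12-bit pairs); both round-trip to within one
#' quantisation step of the 200 adu/mV gain, and the text dialect
#' round-trips exactly.
#'
#' @param record An [ecg_record()].
#' @param path Base path (no extension).
#' @param dialect `"wfdb"` or `"columns"`.
#' @param dat_format WFDB signal format, `"16"` or `"212"`.
#' @return `path`, invisibly.
#' @export
write_ecg_record <- function(record, path, dialect = c("wfdb", "columns"),
                             dat_format = c("16", "212")) {
  stopifnot(inherits(record, "ecg_record"))
  dialect <- match.arg(dialect)
  dat_format <- match.arg(dat_format)
  base <- sub("\\.(hea|dat|apn|txt|yaml)$", "", path)
  switch(dialect,
    wfdb = write_wfdb_record(record, base, dat_format),
    columns = write_columns_record(record, base)
  )
  invisible(path)
}

# ---- columns dialect --------------------------------------------------------

read_columns_record <- function(base) {
  txt <- paste0(base, ".txt")
  side <- paste0(base, ".yaml")
  if (!file.exists(txt)) abort(sprintf("signal file not found: %s", txt))
  if (!file.exists(side)) {
    abort(sprintf("annotation sidecar not found: %s", side))
  }
  cfg <- yaml::read_yaml(side)
  if (is.null(cfg$fs)) abort(sprintf("sidecar %s lacks an `fs` field.", side))
  fs <- as.numeric(cfg$fs)
  if (!is_scalar_number(fs) || fs <= 0) {
    abort(sprintf("sidecar %s: fs must be > 0 (got %s).", side, cfg$fs))
  }
  if (is.null(cfg$labels)) {
    abort(sprintf("sidecar %s lacks a `labels` field.", side))
  }
  labels <- strsplit(as.character(cfg$labels), "")[[1]]
  samples <- scan(txt, what = numeric(), quiet = TRUE)
  ecg_record(samples, fs, check_labels(labels),
             record_id = cfg$record_id %||% basename(base),
             subject_id = cfg$subject_id)
}

write_columns_record <- function(record, base) {
  writeLines(format(record$samples, scientific = FALSE, trim = TRUE,
                    digits = 15),
             paste0(base, ".txt"))
  cfg <- list(
    record_id = record$record_id,
    fs = record$fs,
    labels = paste(record$minute_labels, collapse = "")
  )
  if (!is.null(record$subject_id)) cfg$subject_id <- record$subject_id
  yaml::write_yaml(cfg, paste0(base, ".yaml"))
}

# ---- WFDB dialect -----------------------------------------------------------

# MIT annotation codes used by apnea annotation streams
ANN_NORMAL <- 1L   # symbol "N"
ANN_APNEA <- 8L    # symbol "A"
ANN_SKIP <- 59L    # long-interval escape
ANN_NUM <- 60L
ANN_SUB <- 61L
ANN_CHN <- 62L
ANN_AUX <- 63L

read_wfdb_record <- function(base) {
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) abort(sprintf("header file not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rec_f <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  record_name <- sub("/.*$", "", rec_f[[1]])
  n_sig <- as.integer(rec_f[[2]])
  fs <- if (length(rec_f) >= 3) as.numeric(sub("/.*$", "", rec_f[[3]])) else 250
  if (!is_scalar_number(fs) || fs <= 0) {
    abort(sprintf("header %s: sampling rate must be > 0 (got %s).", hea,
                  rec_f[[3]]))
  }
  n_samp <- if (length(rec_f) >= 4) as.numeric(rec_f[[4]]) else NA_real_
  if (n_sig < 1L) abort(sprintf("header %s declares no signals.", hea))
  sig_f <- strsplit(trimws(lines[[2]]), "\\s+")[[1]]
  dat_file <- sig_f[[1]]
  fmt <- sub("x.*$", "", sig_f[[2]])
  if (!fmt %in% c("16", "212")) {
    abort(sprintf("unsupported WFDB signal format %s (only 16 and 212).", fmt))
  }
  gain <- 200
  baseline <- NA_real_
  adc_zero <- 0
  if (length(sig_f) >= 3) {
    gspec <- sig_f[[3]]                       # e.g. "200", "200(12)/mV"
    gain_num <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gspec))
    if (is.finite(gain_num) && gain_num != 0) gain <- gain_num
    if (grepl("\\(", gspec)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gspec))
    }
  }
  if (length(sig_f) >= 5) adc_zero <- as.numeric(sig_f[[5]])
  if (!is.finite(baseline)) baseline <- adc_zero
  if (!is.finite(baseline)) baseline <- 0

  dat <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat)) abort(sprintf("signal file not found: %s", dat))
  digital <- read_dat_signal(dat, fmt, n_samp)
  if (is.finite(n_samp) && n_samp > 0) digital <- digital[seq_len(n_samp)]

  apn <- paste0(base, ".apn")
  if (!file.exists(apn)) {
    abort(sprintf("annotation file not found: %s", apn))
  }
  labels <- read_apnea_annotations(apn)

  ecg_record((digital - baseline) / gain, fs, labels,
             record_id = record_name)
}

read_dat_signal <- function(path, fmt, n_samp) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (fmt == "16") {
    n <- length(raw) %/% 2L
    readBin(raw[seq_len(2L * n)], "integer", n = n, size = 2L,
            endian = "little", signed = TRUE)
  } else {                                   # 212: 2 samples in 3 bytes
    nb <- length(raw) - length(raw) %% 3L
    b <- as.integer(raw[seq_len(nb)])
    b0 <- b[seq(1L, nb, by = 3L)]
    b1 <- b[seq(2L, nb, by = 3L)]
    b2 <- b[seq(3L, nb, by = 3L)]
    s0 <- b0 + bitwAnd(b1, 15L) * 256L
    s1 <- b2 + bitwAnd(b1 %/% 16L, 15L) * 256L
    s0 <- ifelse(s0 >= 2048L, s0 - 4096L, s0)
    s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
    out <- numeric(2L * length(s0))
    out[c(TRUE, FALSE)] <- s0
    out[c(FALSE, TRUE)] <- s1
    out
  }
}

write_wfdb_record <- function(record, base, dat_format) {
  gain <- 200
  name <- basename(base)
  digital <- round(record$samples * gain)
  lim <- if (dat_format == "212") 2047 else 32767
  digital <- pmin(pmax(digital, -lim - 1), lim)
  writeLines(c(
    sprintf("%s 1 %g %d", name, record$fs, length(digital)),
    sprintf("%s.dat %s %g(0)/mV %d 0 %d 0 0 ECG", name, dat_format, gain,
            if (dat_format == "212") 12L else 16L, as.integer(digital[1]))
  ), paste0(base, ".hea"))

  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con), add = TRUE)
  if (dat_format == "16") {
    writeBin(as.integer(digital), con, size = 2L, endian = "little")
  } else {
    d <- as.integer(digital)
    if (length(d) %% 2L == 1L) d <- c(d, 0L)
    d <- bitwAnd(d, 4095L)                   # 12-bit two's complement
    s0 <- d[c(TRUE, FALSE)]
    s1 <- d[c(FALSE, TRUE)]
    bytes <- integer(3L * length(s0))
    bytes[seq(1L, length(bytes), 3L)] <- bitwAnd(s0, 255L)
    bytes[seq(2L, length(bytes), 3L)] <- bitwAnd(s1 %/% 256L, 15L) * 16L +
      bitwAnd(s0 %/% 256L, 15L)
    bytes[seq(3L, length(bytes), 3L)] <- bitwAnd(s1, 255L)
    writeBin(as.raw(bytes), con)
  }
  write_apnea_annotations(record$minute_labels, 60 * record$fs,
                          paste0(base, ".apn"))
}

# One annotation per minute at sample times 0, 60*fs, 120*fs, ...
# Intervals above 1023 samples use the SKIP escape (code 59) followed by the
# 4-byte interval, high-order 16-bit word first, each word little-endian.
write_apnea_annotations <- function(labels, step, path) {
  words <- integer(0)
  emit <- function(code, interval) c(code * 1024L + as.integer(interval))
  t_prev <- 0
  for (i in seq_along(labels)) {
    t_i <- (i - 1) * step
    delta <- t_i - t_prev
    if (delta > 1023) {
      words <- c(words, emit(ANN_SKIP, 0L),
                 as.integer(delta %/% 65536L), as.integer(delta %% 65536L))
      delta <- 0
    }
    code <- if (labels[i] == "A") ANN_APNEA else ANN_NORMAL
    words <- c(words, emit(code, delta))
    t_prev <- t_i
  }
  words <- c(words, 0L)                      # terminator
  bytes <- as.raw(rbind(words %% 256L, words %/% 256L))
  writeBin(bytes, path)
}

read_apnea_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) %% 2L == 1L) raw <- raw[-length(raw)]
  b <- as.integer(raw)
  lo <- b[c(TRUE, FALSE)]
  hi <- b[c(FALSE, TRUE)]
  words <- lo + 256L * hi
  labels <- character(0)
  i <- 1L
  pending_skip <- 0
  while (i <= length(words)) {
    w <- words[i]
    code <- w %/% 1024L
    interval <- w %% 1024L
    if (w == 0L) break
    if (code == ANN_SKIP) {
      pending_skip <- pending_skip + words[i + 1L] * 65536 + words[i + 2L]
      i <- i + 3L
      next
    }
    if (code == ANN_AUX) {
      i <- i + 1L + ceiling(interval / 2)
      next
    }
    if (code %in% c(ANN_NUM, ANN_SUB, ANN_CHN)) {
      i <- i + 1L
      next
    }
    sym <- if (code == ANN_APNEA) "A" else if (code == ANN_NORMAL) "N" else {
      abort(sprintf(
        "unknown annotation symbol (MIT code %d) in %s.", code, path
      ))
    }
    labels <- c(labels, sym)
    pending_skip <- 0
    i <- i + 1L
  }
  labels
}
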
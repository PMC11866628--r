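# Minimal EDF (European Data Format) I/O: 16-bit integer encoding, one
# 1-second data record per second of signal. Covers the subset of the format
# this package writes; the reader accepts any continuous EDF whose signals
# share a common sampling rate.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

# shortest decimal representation of v that fits in `width` ascii chars
num_ascii <- function(v, width = 8) {
  for (d in seq(7, 1)) {
    s <- formatC(v, digits = d, format = "g", width = 0)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot encode ", v, " in ", width, " chars")
}

#' Write a recording to an EDF file
#'
#' Signals are scaled per channel to the full 16-bit digital range, so the
#' round-trip error is bounded by half a quantization step
#' (`(physmax - physmin) / 65535 / 2` microvolts per channel). The sampling
#' rate must be an integer (one EDF data record per second); a trailing
#' partial second is dropped.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  if (rec$fs != round(rec$fs))
    abort("EDF writer requires an integer sampling rate.")
  fs <- as.integer(rec$fs)
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) abort("recording shorter than one EDF data record (1 s).")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  phys_min <- apply(x, 1, min)
  phys_max <- apply(x, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_max[flat] <- phys_min[flat] + 1
  # encode the physical range exactly as the 8-char header fields will carry
  # it, and quantize against the encoded values, so writer and reader agree
  pmin_str <- vapply(phys_min, num_ascii, "")
  pmax_str <- vapply(phys_max, num_ascii, "")
  phys_min <- as.numeric(pmin_str)
  phys_max <- as.numeric(pmax_str)
  phys_min <- pmin(phys_min, apply(x, 1, min))   # keep data inside the range
  phys_max <- pmax(phys_max, apply(x, 1, max))
  pmin_str <- vapply(phys_min, num_ascii, "")
  pmax_str <- vapply(phys_max, num_ascii, "")
  phys_min <- as.numeric(pmin_str)
  phys_max <- as.numeric(pmax_str)
  dig_min <- -32768L; dig_max <- 32767L
  meta <- paste0("subject=", rec$subject_id, " condition=", rec$condition,
                 " side=", rec$side, " segment=", rec$segment)

  con <- file(path, "wb")
  on.exit(close(con))
  wa <- function(s, w) writeChar(pad_ascii(s, w), con, nchars = w, eos = NULL)
  wa("0", 8); wa("X X X X", 80); wa(meta, 80)
  wa("01.01.26", 8); wa("00.00.00", 8)
  wa(256L + 256L * ns, 8); wa("", 44); wa(n_rec, 8); wa(1L, 8); wa(ns, 4)
  for (lab in rec$labels) wa(paste("EEG", lab), 16)
  for (i in seq_len(ns)) wa("", 80)          # transducer
  for (i in seq_len(ns)) wa("uV", 8)
  for (v in pmin_str) wa(v, 8)
  for (v in pmax_str) wa(v, 8)
  for (i in seq_len(ns)) wa(dig_min, 8)
  for (i in seq_len(ns)) wa(dig_max, 8)
  for (i in seq_len(ns)) wa("", 80)          # prefiltering
  for (i in seq_len(ns)) wa(fs, 8)
  for (i in seq_len(ns)) wa("", 32)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- pmin(pmax(round((x[i, cols] - phys_min[i]) / gain[i]) + dig_min,
                       dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @return `read_recording_edf()` returns an `eeg_recording`; study metadata
#'   is recovered from the recording-identification header field when it was
#'   written by [write_recording_edf()].
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ra <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ra(8); ra(80)
  meta_str <- ra(80)
  ra(8); ra(8); ra(8); ra(44)
  n_rec <- as.integer(ra(8))
  rec_dur <- as.numeric(ra(8))
  ns <- as.integer(ra(4))
  labels <- vapply(seq_len(ns), function(i) sub("^EEG ", "", ra(16)), "")
  for (i in seq_len(ns)) ra(80)
  for (i in seq_len(ns)) ra(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(ra(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(ra(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(ra(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(ra(8)), 0)
  for (i in seq_len(ns)) ra(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(ra(8)), 0L)
  for (i in seq_len(ns)) ra(32)
  if (length(unique(spr / rec_dur)) != 1L)
    abort("EDF signals with differing sampling rates are not supported.")
  fs <- spr[1] / rec_dur

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      cols <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      data[i, cols] <- phys_min[i] + (dig - dig_min[i]) * gain[i]
    }
  }

  grab <- function(key) {
    m <- regmatches(meta_str, regexpr(paste0(key, "=\\S+"), meta_str))
    if (!length(m)) return(NA_character_)
    v <- sub(paste0(key, "="), "", m)
    if (v == "NA") NA_character_ else v
  }
  eeg_recording(data, fs = fs, labels = labels,
                subject_id = grab("subject"), condition = grab("condition"),
                side = grab("side"), segment = grab("segment"))
}
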
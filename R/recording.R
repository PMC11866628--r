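#' Construct a multichannel EEG recording
#'
#' The package's signal container: a channels x samples numeric matrix in
#' microvolts, with a sampling rate and study metadata (subject, condition,
#' side, segment). All downstream stages (cleaning, connectivity, graph
#' metrics) take and return this object until results become tabular.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels character vector of unique channel names, one per row of
#'   `data`. Defaults to the 19 labels of [montage_1020()] when the channel
#'   count matches.
#' @param subject_id,condition,side,segment study metadata. `condition` is
#'   `"active"` or `"sham"`, `side` is `"left"` or `"right"`, `segment` is
#'   `"pre"` or `"post"`; all may be `NA` for free-standing recordings.
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, labels = NULL, subject_id = NA_character_,
                          condition = NA_character_, side = NA_character_,
                          segment = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data))
    abort("`data` must be a numeric channels x samples matrix.")
  if (!all(is.finite(data)))
    abort("`data` contains non-finite values.")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort("`fs` must be a single positive number (Hz).")
  if (is.null(labels)) {
    labels <- if (nrow(data) == 19L) montage_1020()$labels
              else paste0("ch", seq_len(nrow(data)))
  }
  if (length(labels) != nrow(data))
    abort("`labels` length must equal the number of channels (rows).")
  if (anyDuplicated(labels))
    abort("channel `labels` must be unique.")
  if (!is.na(condition) && !condition %in% c("active", "sham"))
    abort("`condition` must be \"active\" or \"sham\".")
  if (!is.na(side) && !side %in% c("left", "right"))
    abort("`side` must be \"left\" or \"right\".")
  if (!is.na(segment) && !segment %in% c("pre", "post"))
    abort("`segment` must be \"pre\" or \"post\".")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, subject_id = subject_id,
         condition = condition, side = side, segment = segment),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  meta <- c(subject = x$subject_id, condition = x$condition,
            side = x$side, segment = x$segment)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# replace the signal matrix, keeping metadata
rec_with_data <- function(rec, data) {
  rec$data <- data
  rownames(rec$data) <- rec$labels
  rec
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Write / read a recording as delimited text
#'
#' One row per channel with a `label` column; a JSON sidecar
#' (`<path>.json`) carries the sampling rate and study metadata.
#'
#' @param rec an `eeg_recording`.
#' @param path file path for the TSV signal table.
#' @return `write_recording_tsv()` returns `path` invisibly;
#'   `read_recording_tsv()` returns an `eeg_recording`.
#' @export
write_recording_tsv <- function(rec, path) {
  df <- data.frame(label = rec$labels, rec$data, check.names = FALSE)
  colnames(df) <- c("label", paste0("s", seq_len(ncol(rec$data))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(fs = rec$fs, subject_id = rec$subject_id,
               condition = rec$condition, side = rec$side,
               segment = rec$segment)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    abort(sprintf("missing metadata sidecar '%s'", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  as_chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  eeg_recording(
    data = as.matrix(df[, -1, drop = FALSE]),
    fs = meta$fs, labels = as.character(df$label),
    subject_id = as_chr(meta$subject_id), condition = as_chr(meta$condition),
    side = as_chr(meta$side), segment = as_chr(meta$segment)
  )
}

#' Read a recording from EDF or delimited text
#'
#' Dispatches on `format` (or the file extension), normalizes channel order
#' to the montage, and errors on missing montage channels, naming them.
#'
#' @param path input file.
#' @param format `"edf"`, `"delimited"`, or `"auto"` (by extension:
#'   `.edf` / anything else).
#' @param montage an [eeg_montage][montage_1020()] giving the required
#'   channel set and order, or `NULL` to accept the file's own channels.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           montage = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf"
              else if (ext %in% c("tsv", "txt", "csv")) "delimited"
              else abort(sprintf("unsupported recording format '.%s'", ext))
  }
  rec <- switch(format,
    edf = read_recording_edf(path),
    delimited = read_recording_tsv(path)
  )
  if (!is.null(montage)) {
    missing_ch <- setdiff(montage$labels, rec$labels)
    if (length(missing_ch))
      abort(paste0("recording is missing montage channel(s): ",
                   paste(missing_ch, collapse = ", ")))
    rec$data <- rec$data[montage$labels, , drop = FALSE]
    rec$labels <- montage$labels
  }
  rec
}
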
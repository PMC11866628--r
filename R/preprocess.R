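#' Zero-phase Butterworth bandpass filter
#'
#' Filters every channel forward and backward (`signal::filtfilt`) with a
#' Butterworth design, giving a zero-phase response; phase distortion would
#' bias downstream coherence phases, so linear-phase behavior is essential
#' here.
#'
#' @param rec an `eeg_recording`.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order (of the underlying lowpass/highpass prototype;
#'   default 4).
#' @return the filtered `eeg_recording`.
#' @export
bandpass <- function(rec, low = 1, high = 55, order = 4) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    abort(sprintf("band edges must satisfy 0 < low < high < fs/2 = %g Hz.", nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  n <- ncol(rec$data)
  pad <- min(n - 1L, as.integer(ceiling(3 * rec$fs / low)))
  out <- t(apply(rec$data, 1, function(x) {
    x <- x - mean(x)                 # DC is outside any passband
    # reflect the ends (even symmetry: no spurious offset plateau) to
    # suppress forward-backward edge transients
    xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
    signal::filtfilt(bf, xp)[(pad + 1L):(pad + n)]
  }))
  rec_with_data(rec, out)
}

new_cleaning_report <- function(segments = NULL, interpolated = character(),
                                removed_components = 0L) {
  if (is.null(segments))
    segments <- tibble::tibble(channel = character(), start = integer(),
                               end = integer(), reason = character(),
                               boundary = logical())
  structure(list(repaired_segments = segments,
                 interpolated_channels = interpolated,
                 removed_components = removed_components),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d repaired segment(s), %d interpolated channel(s), %d removed component(s)\n",
              nrow(x$repaired_segments), length(x$interpolated_channels),
              x$removed_components))
  invisible(x)
}

# contiguous runs of TRUE in a logical vector -> start/end index matrix
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect and repair transient artifacts
#'
#' Flags per channel (i) spike samples whose robust z-score
#' (median/MAD-based) exceeds `spike_z` and (ii) flat segments where the
#' running variance over a `flat_min`-second window stays below `flat_var`.
#' Each flagged run is replaced sample-wise by the 50/50 average of the
#' immediately preceding and subsequent windows of equal length; at a
#' recording boundary only the available side is used and the segment is
#' marked `boundary = TRUE` in the report. Unflagged samples pass through
#' bit-identical.
#'
#' @param rec an `eeg_recording`.
#' @param spike_z robust z-score threshold for spikes.
#' @param flat_min minimum flat-segment duration, seconds.
#' @param flat_var running-variance floor defining "flat", in microvolts^2.
#' @return list with elements `recording` and `report` (a `cleaning_report`).
#' @export
repair_transients <- function(rec, spike_z = 8, flat_min = 0.1,
                              flat_var = 1e-3) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  if (spike_z <= 0 || flat_min <= 0 || flat_var <= 0)
    abort("thresholds must be positive.")
  n <- ncol(rec$data)
  L <- max(2L, as.integer(round(flat_min * rec$fs)))
  out <- rec$data
  segs <- list()
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    s <- mad(x)
    z <- if (s > 0) abs(x - median(x)) / s else rep(0, n)
    spike_mask <- z > spike_z
    # running variance over centered-ish window via cumulative sums
    cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
    if (n >= L) {
      idx <- seq_len(n - L + 1L)
      m <- (cs[idx + L] - cs[idx]) / L
      v <- (cs2[idx + L] - cs2[idx]) / L - m^2
      flat_windows <- which(v < flat_var)
      flat_mask <- rep(FALSE, n)
      for (w in flat_windows) flat_mask[w:(w + L - 1L)] <- TRUE
    } else flat_mask <- rep(FALSE, n)
    # flats take precedence where masks overlap
    for (reason in c("flat", "spike")) {
      mask <- if (reason == "flat") flat_mask else spike_mask & !flat_mask
      if (!any(mask)) next
      runs <- true_runs(mask)
      if (reason == "flat") runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= L, ,
                                         drop = FALSE]
      for (r in seq_len(nrow(runs))) {
        a <- runs[r, "start"]; b <- runs[r, "end"]; len <- b - a + 1L
        prev_ok <- a - len >= 1L
        next_ok <- b + len <= n
        if (prev_ok && next_ok) {
          repl <- 0.5 * x[(a - len):(a - 1L)] + 0.5 * x[(b + 1L):(b + len)]
        } else if (prev_ok) {
          repl <- x[(a - len):(a - 1L)]
        } else if (next_ok) {
          repl <- x[(b + 1L):(b + len)]
        } else next  # run spans the whole recording; nothing to borrow
        out[i, a:b] <- repl
        segs[[length(segs) + 1L]] <- tibble::tibble(
          channel = rec$labels[i], start = a, end = b, reason = reason,
          boundary = !(prev_ok && next_ok))
      }
    }
  }
  report <- new_cleaning_report(
    segments = if (length(segs)) dplyr::bind_rows(segs) else NULL)
  list(recording = rec_with_data(rec, out), report = report)
}

#' Interpolate bad channels from their montage neighbors
#'
#' Replaces each bad channel by the equal-weight mean of its good neighbor
#' channels; good channels are untouched. Errors if a bad channel has no
#' good neighbor.
#'
#' @param rec an `eeg_recording`.
#' @param bad character vector of bad channel labels (possibly empty).
#' @param montage an [eeg_montage][montage_1020()].
#' @return the repaired `eeg_recording`.
#' @export
interpolate_channels <- function(rec, bad, montage = montage_1020()) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  if (length(bad) == 0) return(rec)
  if (!all(bad %in% rec$labels))
    abort(paste0("unknown bad channel(s): ",
                 paste(setdiff(bad, rec$labels), collapse = ", ")))
  out <- rec$data
  for (ch in bad) {
    good <- setdiff(intersect(montage$neighbors[[ch]], rec$labels), bad)
    if (length(good) == 0)
      abort(sprintf("channel %s has no good neighbor to interpolate from.", ch))
    out[ch, ] <- colMeans(rec$data[good, , drop = FALSE])
  }
  rec_with_data(rec, out)
}

#' Flag bad channels by neighbor correlation
#'
#' A channel is flagged when the Pearson correlation between its signal and
#' the mean of its montage neighbors falls below `min_cor`.
#'
#' @param rec an `eeg_recording`.
#' @param montage an [eeg_montage][montage_1020()].
#' @param min_cor correlation floor (default 0.4).
#' @return character vector of flagged channel labels.
#' @export
detect_bad_channels <- function(rec, montage = montage_1020(), min_cor = 0.4) {
  flagged <- character()
  for (ch in intersect(rec$labels, montage$labels)) {
    nb <- intersect(montage$neighbors[[ch]], rec$labels)
    if (!length(nb)) next
    ref <- colMeans(rec$data[nb, , drop = FALSE])
    if (stats::sd(ref) == 0 || stats::sd(rec$data[ch, ]) == 0 ||
        stats::cor(rec$data[ch, ], ref) < min_cor)
      flagged <- c(flagged, ch)
  }
  flagged
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean at every sample, so the per-sample mean
#' of the output is zero. Idempotent.
#'
#' @param rec an `eeg_recording`.
#' @return the re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  if (nrow(rec$data) < 2) abort("average reference needs at least 2 channels.")
  rec_with_data(rec, sweep(rec$data, 2, colMeans(rec$data)))
}

# symmetric FastICA with logcosh contrast on whitened data
fastica_decompose <- function(X, max_iter = 500, tol = 1e-5, seed = 1) {
  n <- nrow(X); m <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / m
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-9
  K <- sum(keep)
  Wwhite <- diag(1 / sqrt(e$values[keep]), K) %*% t(e$vectors[, keep, drop = FALSE])
  Z <- Wwhite %*% Xc
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  W <- qr.Q(qr(matrix(rnorm(K * K), K)))
  sym_decor <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), K) %*% t(s$vectors) %*% W
  }
  W <- sym_decor(W)
  it <- 0L
  repeat {
    it <- it + 1L
    Y <- W %*% Z
    G <- tanh(Y)
    Wn <- G %*% t(Z) / m - diag(rowMeans(1 - G^2), K) %*% W
    Wn <- sym_decor(Wn)
    delta <- max(abs(1 - abs(rowSums(Wn * W))))
    W <- Wn
    if (delta < tol) break
    if (it >= max_iter)
      abort(sprintf("ICA did not converge after %d iterations (delta %.2e).",
                    it, delta))
  }
  S <- W %*% Z                        # components x samples, unit variance
  A <- Xc %*% t(S) %*% solve(tcrossprod(S))  # channels x components mixing
  list(S = S, A = A, mean = mu, iterations = it)
}

#' Remove artifact components by ICA
#'
#' Decomposes the recording into independent components (symmetric FastICA,
#' logcosh contrast, deterministic under `seed`), zeroes components matching
#' the rejection criteria, and re-mixes the remainder. Default criteria
#' target the two classic artifact families: high-kurtosis components
#' (spiky/muscle; robust kurtosis z-score across components > `kurtosis_z`)
#' and ocular components (fraction of component power below `lf_cut` Hz above
#' `lf_ratio` together with mixing weight concentrated on the frontal-pole
#' channels above `frontal_ratio`).
#'
#' @param rec an `eeg_recording` (>= `min_duration` seconds for a stable
#'   decomposition).
#' @param kurtosis_z robust z-score threshold on component kurtosis.
#' @param lf_cut low-frequency cutoff in Hz for the ocular criterion.
#' @param lf_ratio minimum low-frequency power fraction.
#' @param frontal_ratio minimum fraction of absolute mixing weight carried by
#'   frontal-pole channels (Fp1/Fp2).
#' @param min_duration minimum recording length in seconds.
#' @param seed RNG seed for the decomposition's random initial rotation.
#' @return list with elements `recording` and `report`.
#' @export
remove_artifact_components <- function(rec, kurtosis_z = 5, lf_cut = 2,
                                       lf_ratio = 0.6, frontal_ratio = 0.4,
                                       min_duration = 60, seed = 1) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  if (rec_duration(rec) < min_duration)
    abort(sprintf("recording shorter than %g s; too short for a stable decomposition.",
                  min_duration))
  dec <- fastica_decompose(rec$data, seed = seed)
  K <- nrow(dec$S)
  kurt <- apply(dec$S, 1, function(s) mean((s - mean(s))^4) / var(s)^2 - 3)
  kz <- if (mad(kurt) > 0) (kurt - median(kurt)) / mad(kurt) else rep(0, K)
  lf_frac <- apply(dec$S, 1, function(s) {
    p <- Mod(fft(s))^2
    nf <- length(s)
    f <- (seq_len(nf) - 1) * rec$fs / nf
    half <- f <= rec$fs / 2
    sum(p[half & f < lf_cut]) / sum(p[half])
  })
  fp <- which(rec$labels %in% c("Fp1", "Fp2"))
  frontal <- if (length(fp)) {
    colSums(abs(dec$A[fp, , drop = FALSE])) / colSums(abs(dec$A))
  } else rep(0, K)
  reject <- kz > kurtosis_z | (lf_frac > lf_ratio & frontal > frontal_ratio)
  clean <- dec$A[, !reject, drop = FALSE] %*% dec$S[!reject, , drop = FALSE] +
    dec$mean
  list(recording = rec_with_data(rec, clean),
       report = new_cleaning_report(removed_components = sum(reject)))
}

#' Run the full cleaning chain
#'
#' Applies, in fixed order: bandpass filter, transient repair, bad-channel
#' interpolation, common-average re-reference, and ICA-based artifact
#' removal. The order is part of the method and is not configurable.
#'
#' @param rec an `eeg_recording`.
#' @param montage an [eeg_montage][montage_1020()].
#' @param low,high,order bandpass parameters, see [bandpass()].
#' @param spike_z,flat_min transient thresholds, see [repair_transients()].
#' @param bad bad channels to interpolate; `"auto"` (the default) flags them
#'   with [detect_bad_channels()].
#' @param ica `TRUE` to run [remove_artifact_components()]; skipping it is
#'   appropriate for short synthetic recordings with no injected artifacts.
#' @param seed RNG seed forwarded to the decomposition.
#' @return list with elements `recording` and `report`.
#' @export
preprocess_recording <- function(rec, montage = montage_1020(), low = 1,
                                 high = 55, order = 4, spike_z = 8,
                                 flat_min = 0.1, bad = "auto", ica = TRUE,
                                 seed = 1) {
  rec <- bandpass(rec, low, high, order)
  rt <- repair_transients(rec, spike_z = spike_z, flat_min = flat_min)
  rec <- rt$recording
  if (identical(bad, "auto")) {
    bad <- detect_bad_channels(rec, montage)
    if (length(bad) > nrow(rec$data) / 2) {
      warn(paste0("more than half the channels fall below the neighbor-",
                  "correlation floor; treating the criterion as ",
                  "inapplicable and interpolating none."))
      bad <- character()
    }
  }
  rec <- interpolate_channels(rec, bad, montage)
  rec <- rereference_average(rec)
  removed <- 0L
  if (ica) {
    ic <- remove_artifact_components(rec, seed = seed,
                                     min_duration = min(60, rec_duration(rec)))
    rec <- ic$recording
    removed <- ic$report$removed_components
  }
  report <- new_cleaning_report(segments = rt$report$repaired_segments,
                                interpolated = bad,
                                removed_components = removed)
  list(recording = rec, report = report)
}
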
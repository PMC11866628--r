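#' The five canonical EEG frequency bands
#'
#' Band edges are half-open `[low, high)` so the shared edges at 4, 8, 13 and
#' 30 Hz are not double-counted.
#'
#' @return named list of `c(low, high)` pairs in Hz: delta 1-4, theta 4-8,
#'   alpha 8-13, beta 13-30, gamma 30-55.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 55))
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping consecutive epochs; a trailing remainder shorter than
#' `epoch_length` is dropped.
#'
#' @param rec an `eeg_recording`.
#' @param epoch_length epoch duration in seconds (default 10);
#'   `epoch_length * fs` must be whole and not exceed the recording length.
#' @return an `epoch_set`: list with `epochs` (epoch x channel x sample
#'   array), `fs`, `epoch_length`, `labels`.
#' @export
segment_epochs <- function(rec, epoch_length = 10) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  nsamp <- round(epoch_length * rec$fs)
  if (abs(epoch_length * rec$fs - nsamp) > 1e-8)
    abort("`epoch_length * fs` must be a whole number of samples.")
  n_ep <- ncol(rec$data) %/% nsamp
  if (n_ep < 1)
    abort(sprintf("recording (%.1f s) shorter than one %g-s epoch.",
                  rec_duration(rec), epoch_length))
  ep <- array(0, dim = c(n_ep, nrow(rec$data), nsamp))
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- rec$data[, ((e - 1) * nsamp + 1):(e * nsamp)]
  }
  structure(list(epochs = ep, fs = rec$fs, epoch_length = epoch_length,
                 labels = rec$labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], x$epoch_length, x$fs))
  invisible(x)
}

# cache for Slepian tapers keyed by (n, nw, k)
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) sequences
#'
#' Computes the first `k` DPSS tapers of length `n` for time-bandwidth
#' product `nw`, from the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the Slepian sequences. For `n` above 1024 the tapers are
#' computed at 1024 points, spline-interpolated to `n`, and
#' re-orthonormalized — the classical interpolation shortcut, accurate to
#' well below estimator noise for the smooth low-order tapers used here.
#' Results are cached per `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (`half_bandwidth * epoch_length`).
#' @param k number of tapers.
#' @return `n x k` matrix; columns are unit-norm orthogonal tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  hit <- get0(key, envir = .dpss_cache)
  if (!is.null(hit)) return(hit)
  dense_dpss <- function(n, nw, k) {
    t0 <- 0:(n - 1)
    dg <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * nw / n)
    od <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
    Tm <- diag(dg)
    Tm[cbind(1:(n - 1), 2:n)] <- od
    Tm[cbind(2:n, 1:(n - 1))] <- od
    e <- eigen(Tm, symmetric = TRUE)
    v <- e$vectors[, seq_len(k), drop = FALSE]
    # fix sign: symmetric tapers positive mean, antisymmetric positive slope
    for (j in seq_len(k)) {
      s <- sum(v[, j])
      if (abs(s) > 1e-8) { if (s < 0) v[, j] <- -v[, j] }
      else if (v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
    }
    v
  }
  if (n <= 1024) {
    v <- dense_dpss(n, nw, k)
  } else {
    n0 <- 1024L
    v0 <- dense_dpss(n0, nw, k)
    x0 <- seq(0, 1, length.out = n0)
    x1 <- seq(0, 1, length.out = n)
    v <- apply(v0, 2, function(col) spline(x0, col, xout = x1)$y)
    v <- qr.Q(qr(v))
    for (j in seq_len(k)) if (sum(v[, j]) < 0 ||
                              (abs(sum(v[, j])) <= 1e-8 &&
                               v[2, j] - v[1, j] < 0)) v[, j] <- -v[, j]
  }
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  assign(key, v, envir = .dpss_cache)
  v
}

#' Multitaper cross-spectral densities
#'
#' Tapers each epoch with `2 * nw - 1` Slepian sequences, Fourier-transforms,
#' and averages the complex cross-products over tapers and epochs into one
#' channel x channel x frequency cross-spectral array. The diagonal holds the
#' (real, non-negative) power spectra; the array is Hermitian in its channel
#' indices at every frequency.
#'
#' @param ep an [epoch_set][segment_epochs()].
#' @param half_bandwidth spectral half-bandwidth W in Hz; the time-bandwidth
#'   product is `W * epoch_length` (default 0.5 Hz, i.e. nw = 5 and 9 tapers
#'   for 10-s epochs). Must give at least 2 tapers.
#' @return a `cross_spectra` object: list with `S` (complex
#'   `nch x nch x nfreq` array), `freqs` (Hz), `taper_count`, `n_epochs`,
#'   `labels`.
#' @export
cross_spectra_multitaper <- function(ep, half_bandwidth = 0.5) {
  if (!inherits(ep, "epoch_set")) abort("`ep` must be an epoch_set.")
  nw <- half_bandwidth * ep$epoch_length
  if (nw <= 1)
    abort("half_bandwidth * epoch_length must exceed 1.")
  k <- floor(2 * nw - 1)
  if (k < 2)
    abort(sprintf("only %d taper(s) available under the 2TW-1 rule; need >= 2.", k))
  d <- dim(ep$epochs)
  n_ep <- d[1]; nch <- d[2]; nsamp <- d[3]
  tapers <- dpss_tapers(nsamp, nw, k)
  nf <- nsamp %/% 2 + 1
  freqs <- (seq_len(nf) - 1) / ep$epoch_length
  # tapered FFTs of every (epoch, taper) pair, then one cross-product per
  # frequency: S[, , f] = X_f %*% Conj(t(X_f)) / (epochs * tapers)
  Fa <- array(0 + 0i, dim = c(nch, n_ep * k, nf))
  idx <- 0L
  for (e in seq_len(n_ep)) {
    xe <- t(ep$epochs[e, , , drop = TRUE])       # nsamp x nch
    if (nch == 1) xe <- matrix(ep$epochs[e, 1, ], ncol = 1)
    for (j in seq_len(k)) {
      idx <- idx + 1L
      Fa[, idx, ] <- t(stats::mvfft(xe * tapers[, j])[seq_len(nf), ,
                                                      drop = FALSE])
    }
  }
  S <- array(0 + 0i, dim = c(nch, nch, nf))
  for (f in seq_len(nf)) {
    Xf <- Fa[, , f, drop = TRUE]
    if (nch == 1) Xf <- matrix(Fa[1, , f], nrow = 1)
    S[, , f] <- Xf %*% Conj(t(Xf)) / (n_ep * k)
  }
  structure(list(S = S, freqs = freqs, taper_count = k, n_epochs = n_ep,
                 labels = ep$labels),
            class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf("<cross_spectra> %d ch, %d freqs (0-%g Hz), %d tapers x %d epochs\n",
              dim(x$S)[1], length(x$freqs), max(x$freqs), x$taper_count,
              x$n_epochs))
  invisible(x)
}

#' Coherence coefficient magnitude
#'
#' The classical coherence `|Sxy| / sqrt(Sxx * Syy)`, a normalized
#' coefficient between 0 and 1 at every channel pair and frequency.
#'
#' @param cs a [cross_spectra][cross_spectra_multitaper()] object.
#' @return real `nch x nch x nfreq` array in `[0, 1]`.
#' @export
coherence <- function(cs) {
  if (!inherits(cs, "cross_spectra")) abort("`cs` must be a cross_spectra.")
  nch <- dim(cs$S)[1]; nf <- dim(cs$S)[3]
  Sm <- cs$S; dim(Sm) <- c(nch * nch, nf)
  P <- Re(Sm[(seq_len(nch) - 1) * nch + seq_len(nch), , drop = FALSE])
  denom <- sqrt(P[rep(seq_len(nch), times = nch), , drop = FALSE] *
                  P[rep(seq_len(nch), each = nch), , drop = FALSE])
  v <- Mod(Sm) / denom
  v[denom == 0] <- 0
  out <- array(v, dim(cs$S))
  attr(out, "freqs") <- cs$freqs
  out
}

#' Imaginary part of coherency
#'
#' `|Im(Sxy / sqrt(Sxx * Syy))|` per channel pair and frequency — the
#' volume-conduction-insensitive connectivity measure: a purely instantaneous
#' (zero-lag) shared source contributes only to the real part of coherency.
#' Pairs whose cross-spectral phase is 0 (equivalently 2*pi) within
#' `phase_tol` are set to zero, implementing the zero-lag exclusion rule. The
#' diagonal is zero and values lie in `[0, 1]`.
#'
#' @param cs a [cross_spectra][cross_spectra_multitaper()] object.
#' @param phase_tol phase tolerance in radians for the zero-lag exclusion.
#' @param signed keep the sign of the imaginary part instead of its absolute
#'   value (the default absolute value yields the non-negative edge weights
#'   required for sparsity thresholding).
#' @return real `nch x nch x nfreq` array with a `freqs` attribute.
#' @export
imaginary_coherence <- function(cs, phase_tol = 0.01, signed = FALSE) {
  if (!inherits(cs, "cross_spectra")) abort("`cs` must be a cross_spectra.")
  nch <- dim(cs$S)[1]; nf <- dim(cs$S)[3]
  Sm <- cs$S; dim(Sm) <- c(nch * nch, nf)
  diag_idx <- (seq_len(nch) - 1) * nch + seq_len(nch)
  P <- Re(Sm[diag_idx, , drop = FALSE])
  denom <- sqrt(P[rep(seq_len(nch), times = nch), , drop = FALSE] *
                  P[rep(seq_len(nch), each = nch), , drop = FALSE])
  v <- Im(Sm) / denom
  if (!signed) v <- abs(v)
  v[abs(Arg(Sm)) < phase_tol] <- 0   # zero-lag exclusion; 2*pi wraps to 0
  v[denom == 0] <- 0
  v[diag_idx, ] <- 0
  out <- array(v, dim(cs$S))
  attr(out, "freqs") <- cs$freqs
  out
}

#' Average connectivity into band-specific adjacency matrices
#'
#' Means the imaginary-coherence array over the frequency bins whose centers
#' fall in each band's half-open `[low, high)` interval, giving one symmetric
#' non-negative adjacency matrix per band (zero diagonal).
#'
#' @param icoh array from [imaginary_coherence()] (with its `freqs`
#'   attribute), or any real channel x channel x frequency array plus
#'   `freqs`.
#' @param bands named list of `c(low, high)` pairs; default [eeg_bands()].
#' @param freqs frequency grid in Hz; defaults to `attr(icoh, "freqs")`.
#' @param labels channel labels for the matrix dimnames.
#' @return a tibble with columns `band`, `low`, `high`, and an `adjacency`
#'   list-column of channel x channel matrices.
#' @export
band_adjacency <- function(icoh, bands = eeg_bands(),
                           freqs = attr(icoh, "freqs"), labels = NULL) {
  if (is.null(freqs)) abort("`freqs` must be supplied (or attached to `icoh`).")
  rows <- purrr::imap(bands, function(lim, nm) {
    sel <- which(freqs >= lim[1] & freqs < lim[2])
    if (!length(sel))
      abort(sprintf("band %s [%g, %g) contains no frequency bins.",
                    nm, lim[1], lim[2]))
    W <- apply(icoh[, , sel, drop = FALSE], c(1, 2), mean)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    if (!is.null(labels)) dimnames(W) <- list(labels, labels)
    tibble::tibble(band = nm, low = lim[1], high = lim[2],
                   adjacency = list(W))
  })
  out <- dplyr::bind_rows(rows)
  out$band <- factor(out$band, levels = names(bands))
  class(out) <- c("tbl_band_adjacency", class(out))
  out
}

#' Band connectivity straight from a recording
#'
#' Convenience chain: [segment_epochs()] then [cross_spectra_multitaper()]
#' then [imaginary_coherence()] then [band_adjacency()].
#'
#' @param rec an `eeg_recording`.
#' @param epoch_length epoch duration, seconds.
#' @param half_bandwidth multitaper half-bandwidth, Hz.
#' @param bands band table, default [eeg_bands()].
#' @param phase_tol zero-lag exclusion tolerance, radians.
#' @return the [band_adjacency()] tibble.
#' @export
band_connectivity <- function(rec, epoch_length = 10, half_bandwidth = 0.5,
                              bands = eeg_bands(), phase_tol = 0.01) {
  ep <- segment_epochs(rec, epoch_length)
  cs <- cross_spectra_multitaper(ep, half_bandwidth)
  ic <- imaginary_coherence(cs, phase_tol = phase_tol)
  band_adjacency(ic, bands, labels = rec$labels)
}

#' Write band adjacency matrices to labeled CSV files
#'
#' One `adjacency_<band>.csv` per band (row/column headers = channel labels)
#' plus a single `adjacency_bands.json` bundle.
#'
#' @param ba tibble from [band_adjacency()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_band_adjacency <- function(ba, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list()
  for (i in seq_len(nrow(ba))) {
    W <- ba$adjacency[[i]]
    utils::write.csv(W, file.path(dir, sprintf("adjacency_%s.csv", ba$band[i])))
    bundle[[as.character(ba$band[i])]] <-
      list(low = ba$low[i], high = ba$high[i], W = W)
  }
  jsonlite::write_json(bundle, file.path(dir, "adjacency_bands.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
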
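#' Describe one phase-lagged narrowband oscillator
#'
#' An oscillator is a band-limited Gaussian source shared by a set of
#' channels. Channel `i` of the set receives the source rotated by
#' `(i - 1) * phase_lag` radians (a frequency-domain rotation of the analytic
#' signal), so consecutive channels in the set are lagged by `phase_lag`.
#' A nonzero lag is what the imaginary part of coherency detects; a zero lag
#' emulates a purely volume-conducted (instantaneous) shared source.
#'
#' @param freq center frequency in Hz.
#' @param bandwidth full bandwidth in Hz.
#' @param channels channel labels (or indices) sharing the source.
#' @param phase_lag pairwise phase lag between consecutive channels of the
#'   set, in radians, in `[0, pi)`.
#' @param strength coupling strength in `[0, 1]`; scales the source amplitude
#'   relative to the background-noise RMS.
#' @return a list of class `eeg_oscillator`.
#' @export
oscillator <- function(freq, bandwidth, channels, phase_lag = pi / 2,
                       strength = 0.5) {
  if (!is.numeric(strength) || strength < 0 || strength > 1)
    abort("oscillator `strength` must lie in [0, 1].")
  if (!is.numeric(phase_lag) || phase_lag < 0 || phase_lag >= pi)
    abort("oscillator `phase_lag` must lie in [0, pi).")
  if (!is.numeric(freq) || freq <= 0) abort("oscillator `freq` must be > 0 Hz.")
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    abort("oscillator `bandwidth` must be > 0 Hz.")
  if (length(channels) < 1) abort("oscillator `channels` must be non-empty.")
  structure(list(freq = freq, bandwidth = bandwidth, channels = channels,
                 phase_lag = phase_lag, strength = strength),
            class = "eeg_oscillator")
}

#' Specify the generative model for a synthetic EEG recording
#'
#' The generated signal is the sum of (i) per-channel 1/f^`noise_exponent`
#' Gaussian background noise with RMS `10 * noise_level` microvolts, (ii) the
#' band-limited coupled sources of `oscillators` (amplitude
#' `strength * 10` microvolts each), and (iii) an optional instantaneous
#' linear mixing across channels emulating volume conduction.
#'
#' @param n_channels number of channels; 19 selects the 10-20 montage labels.
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds; `fs * duration` must be whole.
#' @param oscillators list of [oscillator()] objects (possibly empty).
#' @param noise_exponent slope of the 1/f background (power ~ f^-exponent).
#' @param noise_level relative background amplitude (1 = 10 uV RMS).
#' @param mixing `"identity"` or a full-rank square matrix applied
#'   sample-wise across channels after signal construction.
#' @return a list of class `coupling_spec`.
#' @export
coupling_spec <- function(n_channels = 19, fs = 500, duration = 420,
                          oscillators = list(), noise_exponent = 1,
                          noise_level = 1, mixing = "identity") {
  if (!is.numeric(n_channels) || n_channels < 2)
    abort("`n_channels` must be at least 2.")
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive sampling rate.")
  if (!is.numeric(duration) || duration <= 0)
    abort("`duration` must be positive (seconds).")
  if (abs(fs * duration - round(fs * duration)) > 1e-8)
    abort("`fs * duration` must be a whole number of samples.")
  if (!is.list(oscillators) ||
      !all(vapply(oscillators, inherits, TRUE, "eeg_oscillator")))
    abort("`oscillators` must be a list of oscillator() objects.")
  if (!is.numeric(noise_exponent) || noise_exponent < 0)
    abort("`noise_exponent` must be >= 0.")
  if (!is.numeric(noise_level) || noise_level < 0)
    abort("`noise_level` must be >= 0.")
  if (!identical(mixing, "identity")) {
    if (!is.matrix(mixing) || nrow(mixing) != ncol(mixing) ||
        nrow(mixing) != n_channels)
      abort("`mixing` must be \"identity\" or an n_channels x n_channels matrix.")
    if (qr(mixing)$rank < n_channels)
      abort("`mixing` matrix must have full rank.")
  }
  structure(list(n_channels = n_channels, fs = fs, duration = duration,
                 oscillators = oscillators, noise_exponent = noise_exponent,
                 noise_level = noise_level, mixing = mixing),
            class = "coupling_spec")
}

# complex analytic narrowband Gaussian source, unit RMS in its real part
narrowband_source <- function(n, fs, freq, bandwidth) {
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= max(freq - bandwidth / 2, 1e-9) & f <= freq + bandwidth / 2 &
          f <= fs / 2
  if (!any(keep))
    abort("oscillator band contains no frequency bins at this length/rate.")
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  k <- sum(keep)
  spec[keep] <- complex(real = rnorm(k), imaginary = rnorm(k))
  z <- fft(spec, inverse = TRUE) / n
  z / stats::sd(Re(z))
}

# 1/f^a Gaussian noise, unit RMS
pink_noise <- function(n, fs, exponent) {
  w <- rnorm(n)
  if (exponent == 0) return(w)
  spec <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]  # fold to physical frequency
  g <- ifelse(f < 1e-9, 0, f^(-exponent / 2))
  x <- Re(fft(spec * g, inverse = TRUE) / n)
  x / stats::sd(x)
}

BASE_AMP_UV <- 10

#' Generate a synthetic multichannel EEG recording
#'
#' Realizes a [coupling_spec()]: background noise plus phase-lagged coupled
#' narrowband sources, optionally passed through an instantaneous mixing
#' matrix. The same `(spec, seed)` pair always yields a bit-identical
#' recording.
#'
#' @param spec a [coupling_spec()].
#' @param seed integer RNG seed.
#' @param ... metadata passed to [eeg_recording()] (`subject_id`,
#'   `condition`, `side`, `segment`).
#' @return an `eeg_recording`, `n_channels x (fs * duration)`.
#' @examples
#' spec <- coupling_spec(n_channels = 4, fs = 100, duration = 10,
#'   oscillators = list(oscillator(10, 2, c(1, 2), pi / 2, 0.8)))
#' rec <- generate_recording(spec, seed = 1)
#' dim(rec)
#' @export
generate_recording <- function(spec, seed, ...) {
  if (!inherits(spec, "coupling_spec")) abort("`spec` must be a coupling_spec.")
  n <- as.integer(round(spec$fs * spec$duration))
  labels <- if (spec$n_channels == 19) montage_1020()$labels
            else paste0("ch", seq_len(spec$n_channels))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  data <- matrix(0, spec$n_channels, n)
  for (i in seq_len(spec$n_channels)) {
    data[i, ] <- BASE_AMP_UV * spec$noise_level *
      pink_noise(n, spec$fs, spec$noise_exponent)
  }
  for (osc in spec$oscillators) {
    idx <- if (is.character(osc$channels)) match(osc$channels, labels)
           else as.integer(osc$channels)
    if (anyNA(idx) || any(idx < 1 | idx > spec$n_channels))
      abort("oscillator `channels` not found in the recording montage.")
    if (osc$strength == 0) next
    z <- narrowband_source(n, spec$fs, osc$freq, osc$bandwidth)
    for (j in seq_along(idx)) {
      rot <- exp(1i * (j - 1) * osc$phase_lag)
      data[idx[j], ] <- data[idx[j], ] +
        BASE_AMP_UV * osc$strength * Re(z * rot)
    }
  }
  if (!identical(spec$mixing, "identity")) data <- spec$mixing %*% data
  eeg_recording(data, fs = spec$fs, labels = labels, ...)
}

#' Apply an instantaneous volume-conduction mixing to a recording
#'
#' Replaces the channel vector at every sample by `mixing %*% x`. Because the
#' mixing is real and instantaneous it adds no phase lag: it inflates
#' ordinary (real-part) coherence but leaves the imaginary part of coherency
#' at its noise floor — the confound the connectivity estimator is built to
#' reject.
#'
#' @param rec an `eeg_recording`.
#' @param mixing square numeric matrix, dimension = channel count.
#' @return the mixed `eeg_recording` (metadata unchanged).
#' @export
mix_sources <- function(rec, mixing) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  if (!is.matrix(mixing) || nrow(mixing) != ncol(mixing) ||
      nrow(mixing) != nrow(rec$data))
    abort("`mixing` must be square with dimension equal to the channel count.")
  rec_with_data(rec, mixing %*% rec$data)
}

#' Describe a pre/post active/sham simulated study
#'
#' Mirrors a crossover intervention protocol: each subject contributes a
#' `pre` and a `post` resting-state recording under each condition
#' (active/sham x left/right). Post-intervention recordings of active
#' conditions receive the `effect`: a coupling-strength increment applied to
#' the oscillator set of one frequency band.
#'
#' @param n_subjects number of subjects (>= 2); the study this emulates
#'   enrolled 26.
#' @param conditions subset of
#'   `c("active-left", "active-right", "sham-left", "sham-right")`.
#' @param effect list with elements `band` (one of `"delta"`, `"theta"`,
#'   `"alpha"`, `"beta"`, `"gamma"`), `increment` (coupling
#'   strength added in post-active segments, `0` for a null study), and
#'   optionally `channels` (labels of the affected subset; all its pairs are
#'   recruited) and `side` (`"left"`, `"right"` or `"both"`; which active
#'   condition is affected). When `channels` is omitted the effect recruits
#'   the montage's neighbor pairs — a scalp-wide local lattice, the coupling
#'   topography that raises both clustering and small-worldness of the
#'   thresholded graph.
#' @param fs,duration recording parameters passed to [coupling_spec()].
#' @param baseline_strength baseline coupling strength of every band network.
#' @param noise_level background-noise scale.
#' @param seed master integer seed; all per-recording seeds derive from it.
#' @return a list of class `study_design`.
#' @export
study_design <- function(n_subjects = 26,
                         conditions = c("active-left", "active-right",
                                        "sham-left", "sham-right"),
                         effect = list(band = "alpha", increment = 0.5,
                                       side = "both"),
                         fs = 500, duration = 420,
                         baseline_strength = 0.25, noise_level = 1,
                         seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    abort("`n_subjects` must be at least 2.")
  all_cond <- c("active-left", "active-right", "sham-left", "sham-right")
  if (!all(conditions %in% all_cond))
    abort("unknown condition label in `conditions`.")
  if (!effect$band %in% names(eeg_bands()))
    abort(sprintf("effect band '%s' is not one of the five EEG bands.",
                  effect$band))
  if (is.null(effect$increment) || effect$increment < 0)
    abort("`effect$increment` must be >= 0.")
  if (is.null(effect$side)) effect$side <- "both"
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 effect = effect, fs = fs, duration = duration,
                 baseline_strength = baseline_strength,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "study_design")
}

# canonical channel subsets carrying each band's coupled network
band_networks <- function() {
  list(delta = c("Fp1", "Fp2", "F3", "Fz", "F4", "F7"),
       theta = c("Fz", "Cz", "F3", "F4", "C3", "C4"),
       alpha = c("O1", "O2", "P3", "Pz", "P4", "T6"),
       beta  = c("C3", "Cz", "C4", "P3", "Pz", "P4"),
       gamma = c("T3", "T4", "T5", "T6", "F7", "F8"))
}

pair_key <- function(ch) paste(sort(ch), collapse = "|")

# channel pairs an injected effect recruits: either all pairs of an explicit
# channel subset, or (default) the montage's neighbor pairs — a scalp
# lattice. Local lattice-like recruitment is the minimal mechanism that
# raises both clustering and the small-world index of the rank-thresholded
# graph; a single dense clique raises null clustering just as fast and fails
# to move sigma.
effect_pairs <- function(effect) {
  if (!is.null(effect$channels)) {
    prs <- utils::combn(effect$channels, 2)
    return(lapply(seq_len(ncol(prs)), function(k) prs[, k]))
  }
  m <- montage_1020()
  out <- list()
  for (ch in m$labels) {
    for (nb in m$neighbors[[ch]]) {
      if (ch < nb) out[[length(out) + 1L]] <- c(ch, nb)
    }
  }
  out
}

# deterministic per-recording seed derived from the master seed
derive_seed <- function(master, ...) {
  idx <- sum(c(...) * 104729^(seq_along(c(...)) - 1)) %% 1048573
  as.integer((as.numeric(master) * 7919 + idx * 131) %% 2147483587)
}

#' Generate a full synthetic study
#'
#' One pre and one post recording per subject per condition. Each subject
#' carries a fixed set of band-specific pair oscillators (all pairs of each
#' band's channel subset, with subject-specific lags and strengths around
#' `baseline_strength`); pre and post segments are independent realizations
#' of the same subject-level process. Post segments of affected active
#' conditions have `effect$increment` added to the coupling strength of
#' every target-band pair within the effect channel set — both the baseline
#' pairs (capped at 1) and the latent new pairs the effect recruits — so the
#' effect widens and strengthens the band's coupled subnetwork, which is
#' what reorganizes the rank-thresholded binary graph.
#'
#' @param design a [study_design()].
#' @return a tibble with columns `subject`, `condition`, `side`, `segment`
#'   and a `recording` list-column of `eeg_recording` objects.
#' @export
generate_study <- function(design) {
  if (!inherits(design, "study_design")) abort("`design` must be a study_design.")
  bands <- eeg_bands()
  nets <- band_networks()
  grid <- tidyr::expand_grid(
    subject = sprintf("S%02d", seq_len(design$n_subjects)),
    cond_full = design$conditions,
    segment = c("pre", "post")
  )
  grid$condition <- sub("-.*$", "", grid$cond_full)
  grid$side <- sub("^.*-", "", grid$cond_full)

  eff_pairs <- effect_pairs(design$effect)
  eff_keys <- vapply(eff_pairs, pair_key, "")

  subject_oscillators <- function(si) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(derive_seed(design$seed, si, 1))
    oscs <- list()
    add_osc <- function(b, pair, strength) {
      lim <- bands[[b]]
      o <- oscillator(freq = mean(lim), bandwidth = min(diff(lim), 4),
                      channels = pair,
                      phase_lag = runif(1, 0.35 * pi, 0.65 * pi),
                      strength = strength)
      attr(o, "band") <- b
      oscs[[length(oscs) + 1L]] <<- o
    }
    for (b in names(bands)) {
      prs <- utils::combn(nets[[b]], 2)
      for (k in seq_len(ncol(prs))) {
        add_osc(b, prs[, k],
                min(1, max(0, design$baseline_strength +
                                runif(1, -0.05, 0.05))))
      }
    }
    # latent effect-band oscillators: the new pairs the effect can recruit,
    # silent (strength 0) unless the increment is applied
    if (design$effect$increment > 0) {
      base_keys <- apply(utils::combn(nets[[design$effect$band]], 2), 2,
                         pair_key)
      for (k in seq_along(eff_pairs)) {
        if (eff_keys[k] %in% base_keys) next
        add_osc(design$effect$band, eff_pairs[[k]], 0)
      }
    }
    oscs
  }

  recs <- vector("list", nrow(grid))
  for (si in seq_len(design$n_subjects)) {
    oscs <- subject_oscillators(si)
    rows <- which(grid$subject == sprintf("S%02d", si))
    for (r in rows) {
      o <- oscs
      affected <- grid$condition[r] == "active" && grid$segment[r] == "post" &&
        design$effect$increment > 0 &&
        (design$effect$side == "both" || design$effect$side == grid$side[r])
      if (affected) {
        for (k in seq_along(o)) {
          if (!identical(attr(o[[k]], "band"), design$effect$band)) next
          if (!(pair_key(o[[k]]$channels) %in% eff_keys)) next
          o[[k]]$strength <- min(1, o[[k]]$strength + design$effect$increment)
        }
      }
      spec <- coupling_spec(n_channels = 19, fs = design$fs,
                            duration = design$duration, oscillators = o,
                            noise_level = design$noise_level)
      recs[[r]] <- generate_recording(
        spec,
        seed = derive_seed(design$seed, si, match(grid$cond_full[r],
                                                  design$conditions) + 1,
                           (grid$segment[r] == "post") + 2),
        subject_id = grid$subject[r], condition = grid$condition[r],
        side = grid$side[r], segment = grid$segment[r])
    }
  }
  tibble::tibble(subject = grid$subject, condition = grid$condition,
                 side = grid$side, segment = grid$segment, recording = recs)
}

#' Construct small benchmark graphs
#'
#' Standard graph families used as oracles for the global topology metrics.
#'
#' @param kind one of `"complete"`, `"star"`, `"ring_lattice"`,
#'   `"watts_strogatz"`, `"erdos_renyi"`, `"path"`.
#' @param n node count (>= 2).
#' @param k even neighborhood degree for lattices (`k < n`).
#' @param p rewiring/edge probability in `[0, 1]`.
#' @param seed RNG seed for the random families.
#' @return a symmetric 0/1 adjacency matrix with zero diagonal.
#' @examples
#' g <- make_fixture_graph("ring_lattice", n = 10, k = 4)
#' rowSums(g)  # every node has degree 4
#' @export
make_fixture_graph <- function(kind = c("complete", "star", "ring_lattice",
                                        "watts_strogatz", "erdos_renyi",
                                        "path"),
                               n, k = NULL, p = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || n < 2) abort("`n` must be at least 2.")
  if (kind %in% c("ring_lattice", "watts_strogatz")) {
    if (is.null(k) || k %% 2 != 0 || k >= n)
      abort("lattice `k` must be even and smaller than `n`.")
  }
  if (kind %in% c("watts_strogatz", "erdos_renyi")) {
    if (is.null(p) || p < 0 || p > 1) abort("`p` must lie in [0, 1].")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  g <- switch(kind,
    complete = igraph::make_full_graph(n),
    star = igraph::make_star(n, mode = "undirected"),
    path = igraph::make_lattice(c(n), circular = FALSE),
    ring_lattice = igraph::sample_smallworld(1, n, k / 2, 0),
    watts_strogatz = igraph::sample_smallworld(1, n, k / 2, p),
    erdos_renyi = igraph::sample_gnp(n, p)
  )
  g <- igraph::simplify(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  storage.mode(a) <- "double"
  dimnames(a) <- NULL
  a
}
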
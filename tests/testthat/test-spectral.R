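test_that("epoching follows the floor rule and validates length", {
  rec <- generate_recording(coupling_spec(n_channels = 3, fs = 100,
                                          duration = 42.5), seed = 1)
  ep <- segment_epochs(rec, epoch_length = 10)
  expect_identical(dim(ep$epochs), c(4L, 3L, 1000L))       # remainder dropped
  expect_identical(ep$epochs[2, , ], unname(rec$data[, 1001:2000]))
  # the full-scale arithmetic this mirrors: 420 s / 10 s -> 42 epochs of 5000
  expect_identical(c(420 %/% 10, 10 * 500), c(42, 5000))
  short <- generate_recording(coupling_spec(n_channels = 3, fs = 100,
                                            duration = 5), seed = 1)
  expect_error(segment_epochs(short, 10), "shorter than")
})

test_that("Slepian tapers are orthonormal and spectrally concentrated", {
  for (n in c(500, 2000)) {   # 2000 exercises the interpolated path
    v <- dpss_tapers(n, nw = 5, k = 9)
    expect_equal(dim(v), c(n, 9))
    expect_equal(crossprod(v), diag(9), tolerance = 1e-8)
    # first taper: nearly all energy within the half-bandwidth W = nw/n
    spec <- Mod(stats::fft(c(v[, 1], rep(0, 7 * n))))^2
    f <- (seq_along(spec) - 1) / (8 * n)
    inband <- sum(spec[f <= 5 / n | f >= 1 - 5 / n]) / sum(spec)
    expect_gt(inband, 0.999)
  }
})

test_that("multitaper cross-spectra are Hermitian with real power spectra", {
  rec <- coupled_pair_rec(seed = 2, fs = 100, duration = 30)
  cs <- cross_spectra_multitaper(segment_epochs(rec, 5), half_bandwidth = 1)
  expect_equal(cs$taper_count, 9)        # 2 * (1 * 5) - 1
  for (f in c(1, 10, 50)) {
    S <- cs$S[, , f]
    expect_equal(S, Conj(t(S)), tolerance = 1e-12)
    expect_true(all(Re(diag(S)) >= 0))
    expect_lt(max(abs(Im(diag(S)))), 1e-12)
  }
  expect_error(cross_spectra_multitaper(segment_epochs(rec, 5),
                                        half_bandwidth = 0.1), "exceed 1")
})

test_that("a pure tone peaks at the nearest frequency bin (periodogram oracle)", {
  fs <- 100
  t <- seq_len(30 * fs) / fs
  x <- rbind(sin(2 * pi * 10.2 * t), stats::rnorm(length(t), sd = 0.1))
  rec <- eeg_recording(x, fs = fs)
  cs <- cross_spectra_multitaper(segment_epochs(rec, 5), half_bandwidth = 0.5)
  pxx <- Re(cs$S[1, 1, ])
  # independent oracle: plain rectangular-window periodogram of one epoch
  per <- Mod(stats::fft(x[1, 1:500]))^2
  oracle_peak <- which.max(per[1:251])
  expect_equal(which.max(pxx), oracle_peak)
  expect_equal(cs$freqs[which.max(pxx)], 10.2, tolerance = 0.2)
})

test_that("imaginary coherence detects quadrature lag and rejects zero lag", {
  fs <- 100
  t <- seq_len(40 * fs) / fs
  set.seed(3)
  base <- cos(2 * pi * 10 * t)
  quad <- sin(2 * pi * 10 * t)
  noise <- function() stats::rnorm(length(t), sd = 0.05)
  rec <- eeg_recording(rbind(base + noise(), quad + noise(), base + noise()),
                       fs = fs)
  cs <- cross_spectra_multitaper(segment_epochs(rec, 5), half_bandwidth = 1)
  ic <- imaginary_coherence(cs)
  bin10 <- which.min(abs(cs$freqs - 10))
  expect_gt(ic[1, 2, bin10], 0.9)        # quarter-cycle lag -> ~1
  expect_lt(ic[1, 3, bin10], 0.2)        # same phase -> excluded / near 0
  expect_true(all(ic >= 0 & ic <= 1))
  expect_true(all(diag(ic[, , bin10]) == 0))

  # identical signals: zero everywhere
  rec2 <- eeg_recording(rbind(base, base), fs = fs)
  ic2 <- imaginary_coherence(cross_spectra_multitaper(segment_epochs(rec2, 5),
                                                      half_bandwidth = 1))
  expect_equal(max(ic2), 0)
})

test_that("coherence magnitude stays in [0, 1] and symmetric", {
  for (s in 1:5) {
    rec <- coupled_pair_rec(seed = s, fs = 100, duration = 20)
    cs <- cross_spectra_multitaper(segment_epochs(rec, 5), half_bandwidth = 1)
    co <- coherence(cs)
    expect_true(all(co >= 0 & co <= 1 + 1e-12))
    expect_equal(co[, , 10], t(co[, , 10]), tolerance = 1e-12)
  }
})

test_that("instantaneous mixing inflates real coherence but not the imaginary part", {
  fs <- 100
  set.seed(42)
  M <- matrix(stats::runif(16, 0.2, 1), 4, 4) + diag(4)
  d_real <- numeric(20); signed_floor <- numeric(20); mixed_mag <- numeric(20)
  for (s in 1:20) {
    spec <- coupling_spec(n_channels = 4, fs = fs, duration = 30,
                          noise_exponent = 0)
    rec <- generate_recording(spec, seed = 100 + s)
    mixed <- mix_sources(rec, M)
    cs_raw <- cross_spectra_multitaper(segment_epochs(rec, 5),
                                       half_bandwidth = 1)
    cs_mix <- cross_spectra_multitaper(segment_epochs(mixed, 5),
                                       half_bandwidth = 1)
    band_mean <- function(arr) {
      mean(apply(arr[, , 10:40], 3, function(W) mean(W[upper.tri(W)])))
    }
    d_real[s] <- band_mean(coherence(cs_mix)) - band_mean(coherence(cs_raw))
    # signed imaginary coherency of the mixture: symmetric about zero
    signed_floor[s] <- band_mean(imaginary_coherence(cs_mix, signed = TRUE))
    mixed_mag[s] <- band_mean(imaginary_coherence(cs_mix))
  }
  expect_lt(stats::t.test(d_real)$p.value, 0.01)  # real part clearly inflated
  expect_gt(mean(d_real), 0.2)
  # signed imaginary part statistically indistinguishable from zero
  expect_gt(stats::t.test(signed_floor)$p.value, 0.01)
  # and its magnitude stays at a small estimator noise floor
  expect_lt(mean(mixed_mag), 0.15)
})

test_that("more epochs lower the uncoupled imaginary-coherence floor", {
  floor_at <- function(n_ep, s) {
    spec <- coupling_spec(n_channels = 3, fs = 100, duration = 5 * n_ep,
                          noise_exponent = 0)
    rec <- generate_recording(spec, seed = s)
    ba <- band_connectivity(rec, epoch_length = 5, half_bandwidth = 1)
    mean(vapply(ba$adjacency, mean_offdiag, 0))
  }
  f10 <- vapply(1:10, function(s) floor_at(10, s), 0)
  f40 <- vapply(1:10, function(s) floor_at(40, s), 0)
  expect_lt(mean(f40), mean(f10))
})

test_that("band averaging yields five matrices with the expected structure", {
  rec <- coupled_pair_rec(seed = 5, fs = 200, duration = 30)
  ba <- band_connectivity(rec, epoch_length = 5, half_bandwidth = 1)
  expect_equal(nrow(ba), 5)
  expect_identical(as.character(ba$band),
                   c("delta", "theta", "alpha", "beta", "gamma"))
  for (W in ba$adjacency) {
    expect_equal(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(W >= 0 & W <= 1))
  }
  # constant array averages to that constant
  freqs <- seq(0, 60, by = 0.5)
  const <- array(0.37, dim = c(3, 3, length(freqs)))
  for (f in seq_along(freqs)) diag(const[, , f]) <- 0
  out <- band_adjacency(const, freqs = freqs)
  expect_true(all(vapply(out$adjacency,
                         function(W) all(W[upper.tri(W)] == 0.37), TRUE)))
  expect_error(band_adjacency(const, bands = list(x = c(200, 300)),
                              freqs = freqs), "no frequency bins")
})
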
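make_rec <- function(data, fs = 100) eeg_recording(data, fs = fs)

test_that("bandpass attenuates out-of-band tones and passes mid-band", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)[-1]
  trim <- (2 * fs):(length(t) - 2 * fs)
  mk <- function(f) make_rec(rbind(sin(2 * pi * f * t),
                                   cos(2 * pi * f * t)), fs)
  # DC blocked entirely
  dc <- bandpass(make_rec(matrix(1, 2, length(t)), fs), 1, 55)
  expect_lt(max(abs(dc$data[, trim])), 1e-6)
  # 10 Hz mid-band within 5% of unity
  mid <- bandpass(mk(10), 1, 55)
  amp <- max(abs(mid$data[1, trim]))
  expect_gt(amp, 0.95); expect_lt(amp, 1.05)
  # 0.2 Hz attenuated by >= 20 dB
  lo <- bandpass(mk(0.2), 1, 55)
  expect_lt(max(abs(lo$data[1, trim])), 0.1)
  expect_error(bandpass(mk(10), 0, 55), "band edges")
  expect_error(bandpass(mk(10), 1, 300), "band edges")
})

test_that("transient repair applies the 50/50 rule and reports bounds", {
  fs <- 100
  x <- sin(2 * pi * 3 * seq(0, 20, by = 1 / fs)[-1])
  rec <- make_rec(rbind(x, x + 0.5), fs)
  # clean input: identity, empty report
  rt <- repair_transients(rec)
  expect_identical(rt$recording$data, rec$data)
  expect_equal(nrow(rt$report$repaired_segments), 0)

  # inject a 200-ms flat run and a large spike
  y <- rec$data
  y[1, 501:520] <- y[1, 500]            # 200 ms flat
  y[2, 1200] <- 60                       # lone spike, >> 8 robust z
  rt <- repair_transients(make_rec(y, fs))
  rep <- rt$report$repaired_segments
  expect_setequal(rep$reason, c("flat", "spike"))
  spike_row <- rep[rep$reason == "spike", ]
  expect_true(spike_row$start <= 1200 && spike_row$end >= 1200)
  flat_row <- rep[rep$reason == "flat", ]
  expect_true(flat_row$start <= 501 && flat_row$end >= 520)
  # spike replacement = mean of neighbors (50/50 of equal-length windows)
  expect_equal(rt$recording$data[2, 1200],
               0.5 * y[2, 1199] + 0.5 * y[2, 1201])
  # samples outside flagged runs are untouched
  expect_identical(rt$recording$data[2, 1:1190], y[2, 1:1190])

  # the 50/50 arithmetic: replacement = mean of the flanking windows
  set.seed(8)
  z <- matrix(stats::rnorm(2 * 1000, sd = 1), 2)
  z[1, 451:500] <- 1 + stats::rnorm(50, sd = 0.1)   # near-constant 1 before
  z[1, 551:600] <- 3 + stats::rnorm(50, sd = 0.1)   # near-constant 3 after
  z[1, 501:550] <- 1.7                  # truly flat run between them
  out <- repair_transients(make_rec(z, fs))$recording
  expect_equal(out$data[1, 501:550],
               0.5 * z[1, 451:500] + 0.5 * z[1, 551:600],
               ignore_attr = TRUE)
  expect_lt(max(abs(out$data[1, 501:550] - 2)), 0.5)
})

test_that("interpolation replaces bad channels by neighbor means", {
  m <- montage_1020()
  base <- matrix(stats::rnorm(19 * 500), 19, 500)
  rec <- eeg_recording(base, fs = 100, labels = m$labels)
  expect_identical(interpolate_channels(rec, character(), m)$data, rec$data)

  out <- interpolate_channels(rec, "Cz", m)
  nb <- m$neighbors$Cz
  expect_equal(out$data["Cz", ], colMeans(base[match(nb, m$labels), ]))
  expect_identical(out$data[setdiff(m$labels, "Cz"), ],
                   rec$data[setdiff(m$labels, "Cz"), ])

  # identical neighbors reproduce the shared signal exactly
  same <- base
  for (ch in nb) same[match(ch, m$labels), ] <- base[1, ]
  rec2 <- eeg_recording(same, fs = 100, labels = m$labels)
  expect_equal(interpolate_channels(rec2, "Cz", m)$data["Cz", ], base[1, ])

  expect_error(interpolate_channels(rec, c("Cz", nb), m), "no good neighbor")
})

test_that("average re-reference zeroes the per-sample mean and is idempotent", {
  rec <- make_rec(matrix(stats::rnorm(5 * 400) + 3, 5, 400))
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  expect_equal(rereference_average(out)$data, out$data, tolerance = 1e-12)
  balanced <- make_rec(rbind(sin(1:100), -sin(1:100)))
  expect_equal(rereference_average(balanced)$data, balanced$data,
               tolerance = 1e-12)
})

# super-Gaussian (Laplace) independent sources mixed across the scalp: the
# kind of spiky multichannel signal an ICA separates cleanly
laplace_rec <- function(seed, n = 8000, fs = 100, n_ch = 19) {
  set.seed(seed)
  S <- matrix(stats::rexp(n_ch * n) * sample(c(-1, 1), n_ch * n, TRUE),
              n_ch, n)
  A <- diag(n_ch) + matrix(stats::runif(n_ch^2, 0, 0.3), n_ch, n_ch)
  eeg_recording(A %*% S, fs = fs, labels = montage_1020()$labels)
}

test_that("ICA removes an injected frontal slow artifact and little else", {
  rec <- laplace_rec(seed = 4)
  t <- seq_len(ncol(rec$data)) / rec$fs
  art <- 60 * sin(2 * pi * 0.5 * t)
  y <- rec$data
  y["Fp1", ] <- y["Fp1", ] + art
  y["Fp2", ] <- y["Fp2", ] + 0.8 * art
  dirty <- eeg_recording(y, fs = rec$fs, labels = rec$labels)

  res <- remove_artifact_components(dirty, seed = 2)
  expect_gte(res$report$removed_components, 1)
  expect_lte(res$report$removed_components, 19)
  v_before <- var(dirty$data["Fp1", ]) + var(dirty$data["Fp2", ])
  v_after <- var(res$recording$data["Fp1", ]) + var(res$recording$data["Fp2", ])
  expect_lt(v_after, 0.5 * v_before)

  # remove-nothing identity: clean data, criteria that nothing can meet
  clean <- laplace_rec(seed = 9)
  res2 <- remove_artifact_components(clean, kurtosis_z = Inf, lf_ratio = 1.1,
                                     seed = 2)
  expect_equal(res2$report$removed_components, 0)
  rel_err <- max(abs(res2$recording$data - clean$data)) /
    max(abs(clean$data))
  expect_lt(rel_err, 1e-6)

  expect_error(remove_artifact_components(coupled_pair_rec(fs = 100,
                                                           duration = 10)),
               "too short")
})

test_that("the full cleaning chain is near-idempotent on clean data", {
  m <- montage_1020()
  oscs <- c(list(oscillator(10, 3, c("O1", "O2", "Pz", "P3", "P4"),
                            pi / 3, 0.9),
                 oscillator(20, 4, c("C3", "Cz", "C4"), pi / 2, 0.8),
                 oscillator(6, 2, c("Fz", "F3", "F4"), pi / 3, 0.8)),
            lapply(m$labels, function(ch) oscillator(15, 6, ch,
                                                     strength = 0.6)))
  # clean = oscillation-dominated with little energy in the filter's
  # transition bands; residual change comes only from re-attenuating those
  spec <- coupling_spec(n_channels = 19, fs = 200, duration = 30,
                        oscillators = oscs, noise_exponent = 0,
                        noise_level = 0.02)
  rec <- generate_recording(spec, seed = 6)
  once <- preprocess_recording(rec, ica = FALSE)$recording
  twice <- preprocess_recording(once, ica = FALSE)$recording
  rel_rms <- sqrt(mean((twice$data - once$data)^2)) /
    sqrt(mean(once$data^2))
  expect_lt(rel_rms, 0.01)
  expect_identical(once$labels, rec$labels)
  expect_identical(once$fs, rec$fs)
})
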
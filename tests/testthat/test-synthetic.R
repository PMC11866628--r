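test_that("generate_recording honors shape, units and determinism", {
  spec <- coupling_spec(n_channels = 19, fs = 500, duration = 4.2)
  rec <- generate_recording(spec, seed = 7)
  expect_identical(dim(rec), c(19L, 2100L))
  expect_identical(rec$labels, montage_1020()$labels)
  expect_true(all(is.finite(rec$data)))
  # full-scale arithmetic of the shape contract: 420 s at 500 Hz
  expect_identical(round(500 * 420), 210000)

  rec2 <- generate_recording(spec, seed = 7)
  expect_identical(rec$data, rec2$data)
  rec3 <- generate_recording(spec, seed = 8)
  expect_false(identical(rec$data, rec3$data))
})

test_that("generate_recording validates its spec, naming the offending field", {
  expect_error(coupling_spec(n_channels = 1), "n_channels")
  expect_error(oscillator(10, 2, 1:2, strength = 1.2), "strength")
  expect_error(oscillator(10, 2, 1:2, phase_lag = pi), "phase_lag")
  expect_error(coupling_spec(mixing = matrix(0, 19, 19)), "full rank")
  expect_error(coupling_spec(n_channels = 4, mixing = diag(3)), "mixing")
})

test_that("zero coupling gives an imaginary-coherence noise floor near zero", {
  floors <- vapply(1:20, function(s) {
    spec <- coupling_spec(n_channels = 4, fs = 100, duration = 40)
    rec <- generate_recording(spec, seed = s)
    ba <- band_connectivity(rec, epoch_length = 4, half_bandwidth = 1)
    mean_offdiag(ba$adjacency[[3]])
  }, 0)
  # |Im coh| of independent noise has positive bias ~ 1/sqrt(dof), dof = 70;
  # the mean floor must sit well below any genuine coupling signal
  expect_lt(mean(floors), 0.15)
  expect_gt(mean(floors), 0)
})

test_that("a coupled pair stands above the uncoupled distribution", {
  coupled <- numeric(12)
  floor95 <- numeric(12)
  for (s in 1:12) {
    rec <- coupled_pair_rec(seed = s, strength = 0.8)
    ba <- band_connectivity(rec, epoch_length = 5, half_bandwidth = 1)
    W <- ba$adjacency[[3]]
    coupled[s] <- W[1, 2]
    floor95[s] <- stats::quantile(W[upper.tri(W)][-1], 0.95)
  }
  expect_true(all(coupled > floor95))
})

test_that("imaginary coherence rises monotonically with coupling strength", {
  strengths <- c(0.2, 0.5, 0.8)
  means <- vapply(strengths, function(st) {
    mean(vapply(1:20, function(s) {
      rec <- coupled_pair_rec(seed = s, strength = st, fs = 100,
                              duration = 30)
      ba <- band_connectivity(rec, epoch_length = 5, half_bandwidth = 1)
      ba$adjacency[[3]][1, 2]
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("mix_sources applies the matrix sample-wise and checks dimensions", {
  rec <- coupled_pair_rec(seed = 3, fs = 100, duration = 10)
  expect_equal(mix_sources(rec, diag(4))$data, rec$data)
  M <- matrix(runif(16, 0.1, 1), 4, 4)
  mixed <- mix_sources(rec, M)
  expect_equal(mixed$data, M %*% rec$data, ignore_attr = TRUE)
  expect_identical(mixed$labels, rec$labels)
  expect_error(mix_sources(rec, diag(3)), "square|dimension")
})

test_that("generate_study produces the full crossover layout, reproducibly", {
  d <- study_design(n_subjects = 3, fs = 100, duration = 10, seed = 5)
  st <- generate_study(d)
  expect_equal(nrow(st), 3 * 4 * 2)
  expect_equal(26 * 4 * 2, 208)  # the emulated study's full count
  counts <- table(st$condition, st$side, st$segment)
  expect_true(all(counts == 3))
  st2 <- generate_study(d)
  expect_identical(
    lapply(st$recording, function(r) r$data),
    lapply(st2$recording, function(r) r$data))
  expect_error(study_design(n_subjects = 1), "n_subjects")
  expect_error(study_design(effect = list(band = "mu", increment = 0.1)),
               "band")
})

test_that("sham post segments share the pre distribution; active post differ", {
  d <- study_design(n_subjects = 2, conditions = c("active-left", "sham-left"),
                    effect = list(band = "alpha", increment = 0.6,
                                  side = "both"),
                    fs = 160, duration = 30, seed = 11)
  st <- generate_study(d)
  alpha_level <- function(rec) {
    ba <- band_connectivity(rec, epoch_length = 5, half_bandwidth = 1)
    mean_offdiag(ba$adjacency[[3]])
  }
  lev <- vapply(st$recording, alpha_level, 0)
  active_post <- lev[st$condition == "active" & st$segment == "post"]
  active_pre <- lev[st$condition == "active" & st$segment == "pre"]
  sham_post <- lev[st$condition == "sham" & st$segment == "post"]
  sham_pre <- lev[st$condition == "sham" & st$segment == "pre"]
  expect_true(all(active_post > active_pre + 0.02))
  expect_lt(abs(mean(sham_post) - mean(sham_pre)), 0.05)
})

test_that("fixture graphs match their defining properties", {
  rl <- make_fixture_graph("ring_lattice", n = 100, k = 10)
  expect_true(all(rowSums(rl) == 10))
  # closed-form ring-lattice clustering 3(k-2)/(4(k-1))
  expect_equal(clustering_coefficient(rl), 3 * (10 - 2) / (4 * (10 - 1)),
               tolerance = 1e-12)

  er_edges <- vapply(1:30, function(s) {
    sum(make_fixture_graph("erdos_renyi", n = 50, p = 0.2, seed = s)) / 2
  }, 0)
  np <- choose(50, 2) * 0.2
  ci <- np + c(-1, 1) * stats::qnorm(0.995) * sqrt(choose(50, 2) * 0.2 * 0.8)
  expect_gt(mean(er_edges), ci[1])
  expect_lt(mean(er_edges), ci[2])

  st <- make_fixture_graph("star", n = 5)
  expect_equal(sort(rowSums(st)), c(1, 1, 1, 1, 4))
  expect_error(make_fixture_graph("ring_lattice", n = 10, k = 3), "even")
  expect_error(make_fixture_graph("erdos_renyi", n = 10, p = 1.5), "p")
})
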
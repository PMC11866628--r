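# shared fixtures, built in code

# a short 4-channel recording with one coupled pair at 10 Hz, quadrature lag
coupled_pair_rec <- function(seed = 1, strength = 0.8, lag = pi / 2,
                             fs = 200, duration = 60) {
  spec <- coupling_spec(
    n_channels = 4, fs = fs, duration = duration,
    oscillators = list(oscillator(10, 2, c(1, 2), lag, strength)))
  generate_recording(spec, seed = seed)
}

# mean off-diagonal band value of an adjacency matrix
mean_offdiag <- function(W) mean(W[upper.tri(W)])

# random symmetric non-negative weight matrix, zero diagonal
random_weights <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# brute-force all-pairs shortest paths (Floyd-Warshall), independent of the
# package's BFS implementation
bf_distances <- function(g) {
  n <- nrow(g)
  D <- ifelse(g > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

bf_clustering <- function(g) {
  n <- nrow(g)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(g[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (g[nb[a], nb[b]] > 0) links <- links + 1
    }
    links / (k * (k - 1) / 2)
  }, 0)
  mean(vals)
}

bf_path_length <- function(g) {
  D <- bf_distances(g)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

bf_global_efficiency <- function(g) {
  D <- bf_distances(g)
  d <- D[upper.tri(D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

bf_local_efficiency <- function(g) {
  n <- nrow(g)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(g[i, ] > 0)
    if (length(nb) < 2) return(0)
    bf_global_efficiency(g[nb, nb, drop = FALSE])
  }, 0))
}
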
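#' Default sparsity grid
#'
#' @return the 19 thresholding levels 0.05, 0.10, ..., 0.95.
#' @export
sparsity_grid <- function() seq(5L, 95L, by = 5L) / 100

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    abort("adjacency must be a square matrix.")
  if (any(adj < 0)) abort("adjacency must be non-negative.")
  if (max(abs(adj - t(adj))) > 1e-12) abort("adjacency must be symmetric.")
  invisible(adj)
}

#' Threshold a weighted adjacency matrix at a sparsity level
#'
#' Keeps the `round(s * n * (n - 1) / 2)` largest-weight edges (round half
#' up) and binarizes. Weight ties are broken by lexicographic channel-pair
#' order, so thresholding is deterministic.
#'
#' @param adj symmetric non-negative weight matrix (zero diagonal).
#' @param s sparsity fraction in `(0, 1]`: the proportion of all possible
#'   edges retained.
#' @return symmetric 0/1 adjacency matrix with zero diagonal and an edge
#'   count of exactly `round(s * n * (n - 1) / 2)`.
#' @examples
#' W <- abs(stats::rnorm(19 * 19)) |> matrix(19, 19)
#' W <- (W + t(W)) / 2; diag(W) <- 0
#' g <- sparsity_threshold(W, 0.05)
#' sum(g) / 2  # round(0.05 * 171) = 9 edges
#' @export
sparsity_threshold <- function(adj, s) {
  check_adjacency(adj)
  if (!is.numeric(s) || s <= 0 || s > 1) abort("`s` must lie in (0, 1].")
  n <- nrow(adj)
  ut <- which(upper.tri(adj))
  w <- adj[ut]
  if (all(w == 0)) abort("all-zero adjacency cannot be thresholded.")
  m <- floor(s * length(ut) + 0.5)
  # upper.tri indices are already in lexicographic (column-major i<j) order,
  # and order() is stable, so ties fall to the lexicographically first pairs
  keep <- ut[order(-w)[seq_len(m)]]
  g <- matrix(0, n, n)
  g[keep] <- 1
  g <- g + t(g)
  dimnames(g) <- dimnames(adj)
  g
}

check_binary <- function(g) {
  if (!is.matrix(g) || nrow(g) != ncol(g))
    abort("graph must be a square adjacency matrix.")
  if (!all(g %in% c(0, 1))) abort("graph must be binary (0/1).")
  if (any(diag(g) != 0)) abort("graph must have no self-loops.")
  if (max(abs(g - t(g))) > 0) abort("graph must be undirected (symmetric).")
  invisible(g)
}

# all-pairs shortest-path lengths of a binary graph by breadth-first
# expansion with boolean matrix products; Inf for unreachable pairs
graph_distances <- function(g) {
  n <- nrow(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  B <- reach
  for (step in seq_len(n - 1)) {
    B <- (B %*% g) > 0
    newly <- B & !reach
    if (!any(newly)) break
    D[newly] <- step
    reach <- reach | newly
  }
  D
}

#' Mean clustering coefficient
#'
#' Per node: the fraction of the node's neighbor pairs that are themselves
#' connected (triangles through the node over `choose(degree, 2)`); nodes
#' with degree < 2 contribute 0. The graph value is the unweighted mean over
#' all nodes.
#'
#' @param g binary symmetric adjacency matrix, zero diagonal.
#' @return value in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  check_binary(g)
  deg <- rowSums(g)
  tri <- diag(g %*% g %*% g) / 2        # triangles through each node
  denom <- deg * (deg - 1) / 2
  ci <- ifelse(denom > 0, tri / denom, 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all connected (reachable) unordered node
#' pairs. Unreachable pairs are excluded from the mean; their count is
#' attached as the `"unreachable_pairs"` attribute. Errors when no pair is
#' connected.
#'
#' @param g binary symmetric adjacency matrix, zero diagonal.
#' @return mean distance (>= 1 for any graph with at least one edge).
#' @export
characteristic_path_length <- function(g) {
  check_binary(g)
  if (nrow(g) < 2) abort("graph must have at least 2 nodes.")
  D <- graph_distances(g)
  d <- D[upper.tri(D)]
  reachable <- is.finite(d)
  if (!any(reachable)) abort("no connected node pair; path length undefined.")
  structure(mean(d[reachable]),
            unreachable_pairs = sum(!reachable))
}

#' Global efficiency
#'
#' Mean over all unordered node pairs of the inverse shortest-path distance,
#' with unreachable pairs contributing 0.
#'
#' @param g binary symmetric adjacency matrix, zero diagonal.
#' @return value in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  check_binary(g)
  if (nrow(g) < 2) abort("graph must have at least 2 nodes.")
  eg_impl(g)
}

eg_impl <- function(g) {
  D <- graph_distances(g)
  d <- D[upper.tri(D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors; nodes with fewer than 2 neighbors contribute 0.
#'
#' @param g binary symmetric adjacency matrix, zero diagonal.
#' @return value in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  check_binary(g)
  n <- nrow(g)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(g[i, ] > 0)
    if (length(nb) < 2) return(0)
    eg_impl(g[nb, nb, drop = FALSE])
  }, 0)
  mean(vals)
}

#' Degree-preserving rewired null graph
#'
#' Randomizes a binary graph by repeated double-edge swaps, preserving every
#' node's degree and the total edge count exactly. This is the null ensemble
#' against which the small-world indices are normalized.
#'
#' @param g binary symmetric adjacency matrix.
#' @param swaps_per_edge number of attempted swaps per edge (default 10).
#' @param seed RNG seed.
#' @return a rewired binary adjacency matrix with the same degree sequence.
#' @export
rewire_null <- function(g, swaps_per_edge = 10, seed = 1) {
  check_binary(g)
  m <- sum(g) / 2
  if (m < 2) {
    warn("fewer than 2 edges; returning the graph unchanged.")
    return(g)
  }
  ig <- igraph::graph_from_adjacency_matrix(g, mode = "undirected")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = ceiling(swaps_per_edge * m)))
  out <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
  storage.mode(out) <- "double"
  dimnames(out) <- dimnames(g)
  out
}

#' Small-world indices against rewired nulls
#'
#' gamma = Cp(g) / mean Cp over `n_null` degree-preserving rewired graphs;
#' lambda = Lp(g) / mean Lp over the same nulls; sigma = gamma / lambda.
#' A sigma above 1 (high clustering with near-random path lengths) is the
#' small-world signature.
#'
#' @param g binary symmetric adjacency matrix.
#' @param n_null size of the null ensemble (>= 2; default 100).
#' @param swaps_per_edge swaps per edge for each null.
#' @param seed RNG seed; null `i` uses a seed derived from it.
#' @return named list with `gamma`, `lambda`, `sigma`, plus the raw `Cp`,
#'   `Lp` and null means.
#' @export
small_world_indices <- function(g, n_null = 100, swaps_per_edge = 10,
                                seed = 1) {
  check_binary(g)
  if (n_null < 2) abort("`n_null` must be at least 2.")
  cp <- clustering_coefficient(g)
  lp <- as.numeric(characteristic_path_length(g))
  null_cp <- numeric(n_null)
  null_lp <- numeric(n_null)
  for (i in seq_len(n_null)) {
    ng <- rewire_null(g, swaps_per_edge, seed = derive_seed(seed, i))
    null_cp[i] <- clustering_coefficient(ng)
    null_lp[i] <- tryCatch(as.numeric(characteristic_path_length(ng)),
                           error = function(e) NA_real_)
  }
  mcp <- mean(null_cp)
  mlp <- mean(null_lp, na.rm = TRUE)
  if (mcp == 0) abort("null ensemble has zero mean clustering; graph too sparse to normalize.")
  gamma_ <- cp / mcp
  lambda_ <- lp / mlp
  list(gamma = gamma_, lambda = lambda_, sigma = gamma_ / lambda_,
       Cp = cp, Lp = lp, null_Cp = mcp, null_Lp = mlp)
}

metric_names <- function(small_world = TRUE) {
  base <- c("Cp", "Lp", "Eg", "Eloc")
  if (small_world) c(base, "gamma", "lambda", "sigma") else base
}

#' Global metrics across the sparsity grid
#'
#' Thresholds a weighted adjacency matrix at every grid level and computes
#' the global topology metrics of the thresholded binary graph: Cp, Lp, Eg,
#' Eloc and (optionally) the null-normalized gamma, lambda and sigma. Levels
#' where a metric is undefined (e.g. no connected pair) are recorded as `NA`,
#' never fabricated.
#'
#' @param adj symmetric non-negative weight matrix.
#' @param grid sparsity levels in `(0, 1]`; default [sparsity_grid()].
#' @param n_null null-ensemble size for the small-world indices.
#' @param seed RNG seed for the null ensembles.
#' @param small_world compute gamma/lambda/sigma (set `FALSE` to skip the
#'   null ensembles when only the raw metrics are needed).
#' @param swaps_per_edge swaps per edge for each null.
#' @return a tibble with columns `sparsity`, `metric`, `value`.
#' @export
sweep_metrics <- function(adj, grid = sparsity_grid(), n_null = 100, seed = 1,
                          small_world = TRUE, swaps_per_edge = 10) {
  check_adjacency(adj)
  if (length(grid) == 0) abort("sparsity `grid` must be non-empty.")
  if (any(grid <= 0 | grid > 1)) abort("sparsity levels must lie in (0, 1].")
  if (is.unsorted(grid, strictly = TRUE)) abort("`grid` must be strictly increasing.")
  rows <- purrr::map(seq_along(grid), function(gi) {
    s <- grid[gi]
    g <- sparsity_threshold(adj, s)
    safe <- function(expr) tryCatch(as.numeric(expr), error = function(e) NA_real_)
    vals <- c(Cp = safe(clustering_coefficient(g)),
              Lp = safe(characteristic_path_length(g)),
              Eg = safe(global_efficiency(g)),
              Eloc = safe(local_efficiency(g)))
    if (small_world) {
      sw <- tryCatch(
        small_world_indices(g, n_null, swaps_per_edge,
                            seed = derive_seed(seed, gi)),
        error = function(e) list(gamma = NA_real_, lambda = NA_real_,
                                 sigma = NA_real_))
      vals <- c(vals, gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
    }
    tibble::tibble(sparsity = s, metric = names(vals), value = unname(vals))
  })
  out <- dplyr::bind_rows(rows)
  out$metric <- factor(out$metric, levels = metric_names(small_world))
  out
}

#' Metric curves for every frequency band
#'
#' Runs [sweep_metrics()] on each band's adjacency matrix.
#'
#' @param ba tibble from [band_adjacency()].
#' @param ... passed to [sweep_metrics()].
#' @return a tibble with columns `band`, `sparsity`, `metric`, `value`.
#' @export
band_metric_curves <- function(ba, ...) {
  dplyr::bind_rows(purrr::map(seq_len(nrow(ba)), function(i) {
    dplyr::mutate(sweep_metrics(ba$adjacency[[i]], ...),
                  band = ba$band[i], .before = 1)
  }))
}
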
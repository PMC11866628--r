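#' Pipeline configuration
#'
#' Bundles every knob of the study analysis in one validated object, so a run
#' is reproducible from (config, seed) alone.
#'
#' @param epoch_length epoch duration in seconds (default 10).
#' @param half_bandwidth multitaper half-bandwidth in Hz (default 0.5, i.e.
#'   time-bandwidth 5 and 9 tapers on 10-s epochs).
#' @param bands band table, default [eeg_bands()].
#' @param grid sparsity grid, default [sparsity_grid()] (0.05-0.95, 19
#'   levels).
#' @param n_null null-ensemble size for gamma/lambda/sigma (default 100).
#' @param small_world compute the null-normalized indices (default `TRUE`).
#' @param alpha significance criterion (default 0.05).
#' @param preprocess run the cleaning chain on every recording (`TRUE`), or
#'   accept recordings as given (`FALSE`, appropriate when the input is
#'   already clean, e.g. artifact-free synthetic data).
#' @param ica include the ICA artifact-removal stage in the cleaning chain.
#'   Defaults to `FALSE`: synthetic recordings carry no ocular or muscle
#'   components, and the stage is by far the most expensive.
#' @param phase_tol zero-lag exclusion tolerance in radians.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(epoch_length = 10, half_bandwidth = 0.5,
                            bands = eeg_bands(), grid = sparsity_grid(),
                            n_null = 100, small_world = TRUE, alpha = 0.05,
                            preprocess = TRUE, ica = FALSE, phase_tol = 0.01,
                            seed = 1) {
  if (any(grid <= 0 | grid > 1) || is.unsorted(grid, strictly = TRUE))
    abort("`grid` must be strictly increasing within (0, 1].")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(list(epoch_length = epoch_length,
                 half_bandwidth = half_bandwidth, bands = bands, grid = grid,
                 n_null = n_null, small_world = small_world, alpha = alpha,
                 preprocess = preprocess, ica = ica, phase_tol = phase_tol,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# small stable config fingerprint (FNV-1a over the deparsed config)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full study analysis
#'
#' Executes the stages in fixed order for every recording — cleaning chain,
#' epoching, multitaper cross-spectra, imaginary coherence, band adjacency,
#' sparsity-swept graph metrics — then the active-vs-sham paired comparison
#' of normalized pre/post change. Deterministic under `(cfg, seed)`.
#'
#' @param study tibble with columns `subject`, `condition`, `side`,
#'   `segment` and either a `recording` list-column of `eeg_recording`
#'   objects (e.g. from [generate_study()]) or a `path` column of EDF /
#'   delimited files; every (subject, condition, side) must have both a
#'   `pre` and a `post` row.
#' @param cfg a [pipeline_config()].
#' @param keep_adjacency retain each recording's band adjacency matrices in
#'   the result (off by default to keep the result small).
#' @return an `eeg_study_result`: list with `curves` (long tibble: subject,
#'   condition, side, segment, band, sparsity, metric, value), `comparison`
#'   (an `eeg_comparison`), `adjacency` (optional), `reports` (cleaning
#'   reports), and `manifest` (config hash, seed, counts).
#' @export
run_pipeline <- function(study, cfg = pipeline_config(),
                         keep_adjacency = FALSE) {
  need <- c("subject", "condition", "side", "segment")
  if (!all(need %in% names(study)))
    abort(paste0("`study` must have columns: ", paste(need, collapse = ", ")))
  if (!("recording" %in% names(study)) && !("path" %in% names(study)))
    abort("`study` needs a `recording` or `path` column.")
  key <- dplyr::distinct(study[, c("subject", "condition", "side")])
  for (i in seq_len(nrow(key))) {
    segs <- study$segment[study$subject == key$subject[i] &
                          study$condition == key$condition[i] &
                          study$side == key$side[i]]
    missing_seg <- setdiff(c("pre", "post"), segs)
    if (length(missing_seg))
      abort(sprintf("subject %s, %s-%s is missing its %s segment.",
                    key$subject[i], key$condition[i], key$side[i],
                    paste(missing_seg, collapse = "+")))
  }

  curves <- vector("list", nrow(study))
  adjs <- if (keep_adjacency) vector("list", nrow(study)) else NULL
  reports <- vector("list", nrow(study))
  for (i in seq_len(nrow(study))) {
    rec <- if ("recording" %in% names(study)) study$recording[[i]]
           else read_recording(study$path[i])
    stage <- "preprocess"
    res <- tryCatch({
      if (cfg$preprocess) {
        pp <- preprocess_recording(rec, ica = cfg$ica,
                                   seed = derive_seed(cfg$seed, i, 11))
        rec <- pp$recording
        reports[[i]] <- pp$report
      }
      stage <- "connectivity"
      ba <- band_connectivity(rec, epoch_length = cfg$epoch_length,
                              half_bandwidth = cfg$half_bandwidth,
                              bands = cfg$bands, phase_tol = cfg$phase_tol)
      if (keep_adjacency) adjs[[i]] <- ba
      stage <- "metrics"
      band_metric_curves(ba, grid = cfg$grid, n_null = cfg$n_null,
                         seed = derive_seed(cfg$seed, i, 12),
                         small_world = cfg$small_world)
    }, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed for subject %s (%s-%s %s): %s",
                    stage, study$subject[i], study$condition[i],
                    study$side[i], study$segment[i], conditionMessage(e)))
    })
    curves[[i]] <- dplyr::mutate(res, subject = study$subject[i],
                                 condition = study$condition[i],
                                 side = study$side[i],
                                 segment = study$segment[i], .before = 1)
  }
  curves <- dplyr::bind_rows(curves)
  stage <- "statistics"
  comparison <- compare_conditions(curves, alpha = cfg$alpha)
  structure(list(curves = curves, comparison = comparison,
                 adjacency = if (keep_adjacency) adjs,
                 reports = reports,
                 manifest = list(config_hash = config_hash(cfg),
                                 seed = cfg$seed,
                                 n_recordings = nrow(study),
                                 n_subjects = length(unique(study$subject)),
                                 package_version =
                                   as.character(utils::packageVersion("eegraph")))),
            class = "eeg_study_result")
}

#' @export
print.eeg_study_result <- function(x, ...) {
  cat(sprintf("<eeg_study_result> %d recordings, %d subjects (config %s, seed %d)\n",
              x$manifest$n_recordings, x$manifest$n_subjects,
              x$manifest$config_hash, x$manifest$seed))
  print(x$comparison)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x an `eeg_study_result`.
#' @param ... unused.
#' @method tidy eeg_study_result
#' @export
tidy.eeg_study_result <- function(x, ...) x$comparison$map

#' @rdname run_pipeline
#' @method glance eeg_study_result
#' @export
glance.eeg_study_result <- function(x, ...) glance(x$comparison)

#' Write a result bundle to a directory
#'
#' Long-format metric curves, the significance map and summary, per-recording
#' cleaning counts, and a JSON run manifest (config hash, seed, versions).
#'
#' @param result an `eeg_study_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$curves, file.path(dir, "metric_curves.csv"),
                   row.names = FALSE)
  write_comparison(result$comparison, dir)
  jsonlite::write_json(result$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
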
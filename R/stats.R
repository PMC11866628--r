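#' Normalized pre-to-post change of metric curves
#'
#' Elementwise `(post - pre) / pre` over matching (band, sparsity, metric)
#' cells — the within-arm normalization that puts active and sham changes on
#' a common, baseline-free scale. Cells with a zero or missing pre-value are
#' returned as `NA` with a `reason` column, never as infinities.
#'
#' @param pre,post metric-curve tibbles (columns `band`, `sparsity`,
#'   `metric`, `value`) sharing the same grid, bands and metrics.
#' @return tibble with columns `band`, `sparsity`, `metric`, `pre`, `post`,
#'   `change`, `reason` (`NA` when defined).
#' @examples
#' pre <- tibble::tibble(band = "alpha", sparsity = 0.5, metric = "Cp",
#'                       value = 0.5)
#' post <- dplyr::mutate(pre, value = 0.6)
#' normalized_change(pre, post)$change  # 0.2
#' @export
normalized_change <- function(pre, post) {
  key <- c("band", "sparsity", "metric")
  if (!all(key %in% names(pre)) || !all(key %in% names(post)))
    abort("`pre` and `post` must have band, sparsity and metric columns.")
  if (nrow(pre) != nrow(post) ||
      nrow(dplyr::anti_join(pre[key], post[key], by = key)) > 0)
    abort("`pre` and `post` do not share the same band/sparsity/metric grid.")
  joined <- dplyr::inner_join(
    dplyr::rename(pre, pre = "value"),
    dplyr::select(dplyr::rename(post, post = "value"),
                  dplyr::all_of(c(key, "post"))),
    by = key)
  dplyr::mutate(
    joined,
    change = dplyr::if_else(!is.na(.data$pre) & .data$pre != 0 &
                              !is.na(.data$post),
                            (.data$post - .data$pre) / .data$pre, NA_real_),
    reason = dplyr::case_when(
      is.na(.data$pre) | is.na(.data$post) ~ "metric undefined",
      .data$pre == 0 ~ "zero pre-value",
      TRUE ~ NA_character_))
}

#' Paired (dependent-samples) t-test with degenerate-input guards
#'
#' Two-sided t-test on within-subject differences. Subjects with a missing
#' value in either arm are excluded pairwise; fewer than 3 complete pairs, or
#' zero variance of the differences, yields a missing result with a reason
#' instead of an error.
#'
#' @param active,sham numeric vectors, same subjects in the same order.
#' @return list with `t`, `p`, `n_pairs`, `reason` (`NA` when the test ran).
#' @export
paired_test <- function(active, sham) {
  if (length(active) != length(sham))
    abort("`active` and `sham` must have the same length (same subjects).")
  ok <- is.finite(active) & is.finite(sham)
  d <- active[ok] - sham[ok]
  n <- length(d)
  if (n < 3)
    return(list(t = NA_real_, p = NA_real_, n_pairs = n,
                reason = "fewer than 3 complete pairs"))
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, n_pairs = n, reason = NA_character_))
    return(list(t = NA_real_, p = NA_real_, n_pairs = n,
                reason = "degenerate variance"))
  }
  tt <- stats::t.test(active[ok], sham[ok], paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, n_pairs = n,
       reason = NA_character_)
}

#' Compare active and sham normalized changes across the study
#'
#' For each stimulation side, computes per-subject normalized changes
#' ([normalized_change()]) in both arms and runs a paired t-test per
#' (metric, band, sparsity) cell — side-matched (left active vs left sham,
#' right active vs right sham). No multiple-comparison correction is applied;
#' the map reports raw p-values so corrections can be applied downstream.
#'
#' @param curves long tibble of per-recording metric curves with columns
#'   `subject`, `condition` (`"active"`/`"sham"`), `side`, `segment`
#'   (`"pre"`/`"post"`), `band`, `sparsity`, `metric`, `value` — the shape
#'   produced by [run_pipeline()].
#' @param alpha significance criterion on the raw p-value (default 0.05).
#' @return an `eeg_comparison` object; its `map` tibble has one row per
#'   (side, band, metric, sparsity) with `t`, `p`, `n_pairs`, the arm means
#'   of normalized change, and `significant = p < alpha`. Use [tidy()] /
#'   [glance()] / [summarize_significance()] on it.
#' @export
compare_conditions <- function(curves, alpha = 0.05) {
  need <- c("subject", "condition", "side", "segment", "band", "sparsity",
            "metric", "value")
  if (!all(need %in% names(curves)))
    abort(paste0("`curves` must have columns: ", paste(need, collapse = ", ")))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort("`alpha` must lie in (0, 1).")

  wide <- tidyr::pivot_wider(curves, names_from = "segment",
                             values_from = "value")
  if (!all(c("pre", "post") %in% names(wide)))
    abort("`curves` must contain both pre and post segments.")
  chg <- dplyr::mutate(
    wide,
    change = dplyr::if_else(!is.na(.data$pre) & .data$pre != 0 &
                              !is.na(.data$post),
                            (.data$post - .data$pre) / .data$pre, NA_real_))
  arms <- tidyr::pivot_wider(
    dplyr::select(chg, dplyr::all_of(c("subject", "condition", "side", "band",
                                       "sparsity", "metric", "change"))),
    names_from = "condition", values_from = "change")
  if (!all(c("active", "sham") %in% names(arms)))
    abort("both active and sham arms are required for each side.")
  bad <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(arms, .data$side),
                     miss = sum(is.na(.data$active) & is.na(.data$sham)) ==
                       dplyr::n()),
    .data$miss)
  if (nrow(bad)) abort("unmatched active/sham arms for at least one side.")

  map <- dplyr::reframe(
    dplyr::group_by(arms, .data$side, .data$band, .data$metric,
                    .data$sparsity),
    {
      act <- .data$active; shm <- .data$sham
      res <- paired_test(act, shm)
      ok <- is.finite(act) & is.finite(shm)
      tibble::tibble(n_pairs = res$n_pairs, t = res$t, p = res$p,
                     mean_active = mean(act[ok]),
                     mean_sham = mean(shm[ok]),
                     reason = res$reason)
    })
  map <- dplyr::mutate(map, significant = !is.na(.data$p) & .data$p < alpha)
  structure(list(map = map, alpha = alpha,
                 n_subjects = length(unique(curves$subject))),
            class = "eeg_comparison")
}

#' @export
print.eeg_comparison <- function(x, ...) {
  cat(sprintf("<eeg_comparison> %d cells tested at alpha = %g; %d significant\n",
              nrow(x$map), x$alpha, sum(x$map$significant, na.rm = TRUE)))
  print(summarize_significance(x), ...)
  invisible(x)
}

#' @rdname compare_conditions
#' @param x an `eeg_comparison`.
#' @param ... unused.
#' @method tidy eeg_comparison
#' @export
tidy.eeg_comparison <- function(x, ...) x$map

#' @rdname compare_conditions
#' @method glance eeg_comparison
#' @export
glance.eeg_comparison <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$map),
    n_significant = sum(x$map$significant, na.rm = TRUE),
    flag_rate = mean(x$map$significant, na.rm = TRUE),
    alpha = x$alpha,
    n_subjects = x$n_subjects)
}

#' Summarize significant cells as contiguous sparsity ranges
#'
#' Collapses the significance map to one row per (side, band, metric) with a
#' direction (sign of the mean active-minus-sham normalized change over the
#' significant cells) and the contiguous significant sparsity ranges — the
#' compact table view of which metrics an intervention moved, where.
#'
#' @param cmp an `eeg_comparison` from [compare_conditions()].
#' @return tibble with columns `side`, `band`, `metric`, `direction`
#'   (`"up"`/`"down"`), `n_cells`, `sparsity_ranges` (e.g. `"0.30-0.90"`).
#' @export
summarize_significance <- function(cmp) {
  stopifnot(inherits(cmp, "eeg_comparison"))
  sig <- dplyr::filter(cmp$map, .data$significant)
  if (!nrow(sig))
    return(tibble::tibble(side = character(), band = character(),
                          metric = character(), direction = character(),
                          n_cells = integer(), sparsity_ranges = character()))
  grid <- sort(unique(cmp$map$sparsity))
  step_rank <- function(s) match(s, grid)
  dplyr::reframe(
    dplyr::group_by(sig, .data$side, .data$band, .data$metric),
    {
      ord <- order(.data$sparsity)
      s <- .data$sparsity[ord]
      delta_arm <- .data$mean_active - .data$mean_sham
      r <- step_rank(s)
      grp <- cumsum(c(1, diff(r) != 1))
      ranges <- vapply(split(s, grp), function(v) {
        if (length(v) == 1) sprintf("%.2f", v[1])
        else sprintf("%.2f-%.2f", min(v), max(v))
      }, "")
      tibble::tibble(
        direction = if (mean(delta_arm) > 0) "up" else "down",
        n_cells = length(s),
        sparsity_ranges = paste(ranges, collapse = ", "))
    })
}

#' Write a significance map and its summary to disk
#'
#' @param cmp an `eeg_comparison`.
#' @param dir output directory.
#' @return `dir`, invisibly. Writes `significance_map.csv`,
#'   `significance_summary.json` and `significance_summary.md`.
#' @export
write_comparison <- function(cmp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cmp$map, file.path(dir, "significance_map.csv"),
                   row.names = FALSE)
  summ <- summarize_significance(cmp)
  jsonlite::write_json(summ, file.path(dir, "significance_summary.json"),
                       digits = NA)
  md <- c("| Side | Band | Metric | Direction | Sparsity ranges |",
          "|---|---|---|---|---|",
          sprintf("| %s | %s | %s | %s | %s |", summ$side, summ$band,
                  summ$metric, summ$direction, summ$sparsity_ranges))
  writeLines(md, file.path(dir, "significance_summary.md"))
  invisible(dir)
}
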
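#' Plot adjacency matrices per band
#'
#' Heatmaps of the band-specific connectivity matrices, one facet per band —
#' the standard view of a banded functional-connectivity analysis.
#'
#' @param object tibble from [band_adjacency()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tbl_band_adjacency
#' @export
autoplot.tbl_band_adjacency <- function(object, ...) plot_band_adjacency(object)

#' @rdname autoplot.tbl_band_adjacency
#' @param ba tibble from [band_adjacency()].
#' @export
plot_band_adjacency <- function(ba) {
  long <- dplyr::bind_rows(purrr::map(seq_len(nrow(ba)), function(i) {
    W <- ba$adjacency[[i]]
    labs <- rownames(W)
    if (is.null(labs)) labs <- paste0("ch", seq_len(nrow(W)))
    tibble::tibble(band = ba$band[i],
                   from = factor(rep(labs, times = ncol(W)), levels = labs),
                   to = factor(rep(labs, each = nrow(W)), levels = rev(labs)),
                   weight = as.vector(W))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$from, y = .data$to,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~band, nrow = 1) +
    ggplot2::scale_fill_viridis_c(name = "|Im coh|") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot normalized-change curves, active vs sham
#'
#' Group mean +/- standard error of the normalized pre-to-post change as a
#' function of sparsity, one line per arm, with significant sparsity levels
#' starred — the per-metric, per-band comparison view.
#'
#' @param result an `eeg_study_result` from [run_pipeline()].
#' @param band,metric which cell to plot (e.g. `"alpha"`, `"Cp"`).
#' @param side stimulation side to plot (default `"left"`).
#' @return a ggplot object.
#' @export
plot_change_curves <- function(result, band, metric, side = "left") {
  stopifnot(inherits(result, "eeg_study_result"))
  wide <- tidyr::pivot_wider(result$curves, names_from = "segment",
                             values_from = "value")
  chg <- dplyr::filter(
    dplyr::mutate(wide, change = (.data$post - .data$pre) / .data$pre),
    .data$band == !!band, .data$metric == !!metric, .data$side == !!side,
    is.finite(.data$change))
  summ <- dplyr::summarise(
    dplyr::group_by(chg, .data$condition, .data$sparsity),
    mean = mean(.data$change), se = stats::sd(.data$change) / sqrt(dplyr::n()),
    .groups = "drop")
  sig <- dplyr::filter(result$comparison$map, .data$band == !!band,
                       .data$metric == !!metric, .data$side == !!side,
                       .data$significant)
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$sparsity, y = .data$mean,
                                          color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.2) +
    ggplot2::scale_color_manual(values = c(active = "#c0392b",
                                           sham = "#2980b9")) +
    ggplot2::labs(x = "sparsity", y = "normalized change",
                  title = sprintf("%s, %s band (%s side)", metric, band, side)) +
    ggplot2::theme_minimal()
  if (nrow(sig)) {
    ymax <- max(summ$mean + summ$se)
    p <- p + ggplot2::annotate("text", x = sig$sparsity, y = ymax * 1.08,
                               label = "*", size = 5)
  }
  p
}

#' Plot the significance map
#'
#' Tile map of the paired-test p-values over (sparsity x metric), faceted by
#' band and side, with significant cells starred.
#'
#' @param object an `eeg_comparison` from [compare_conditions()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot eeg_comparison
#' @export
autoplot.eeg_comparison <- function(object, ...) {
  m <- dplyr::mutate(object$map, logp = -log10(pmax(.data$p, 1e-16)))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$sparsity, y = .data$metric,
                                  fill = .data$logp)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = dplyr::filter(m, .data$significant),
                       ggplot2::aes(label = "*"), color = "white", size = 3) +
    ggplot2::facet_grid(.data$side ~ .data$band) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = "sparsity", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @method autoplot eeg_study_result
#' @export
autoplot.eeg_study_result <- function(object, ...) autoplot(object$comparison)
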
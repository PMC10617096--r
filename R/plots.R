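#' Heatmap of perturbation effect sizes
#' @param object an [effect_matrix].
#' @param ... unused.
#' @return a ggplot object (targets x features tile map).
#' @method autoplot effect_matrix
#' @export
autoplot.effect_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$feature, .data$target,
                                 fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = object$feature_kind, y = "perturbation",
                  fill = "effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Module-map edge diagram
#'
#' Perturbation modules on the left, regulon modules on the right, one
#' segment per retained edge, line width proportional to -log10 adjusted
#' p-value, colour by sign class.
#'
#' @param edges tibble from [build_module_map()].
#' @return a ggplot object.
#' @export
plot_module_map <- function(edges) {
  if (!nrow(edges)) stop("no edges to plot", call. = FALSE)
  pm <- sort(unique(edges$from_module))
  rm_ <- sort(unique(edges$to_module))
  edges |>
    dplyr::mutate(y_from = match(.data$from_module, pm),
                  y_to = match(.data$to_module, rm_)) |>
    ggplot2::ggplot() +
    ggplot2::geom_segment(ggplot2::aes(
      x = 0, xend = 1, y = .data$y_from, yend = .data$y_to,
      linewidth = .data$weight, colour = .data$sign_class)) +
    ggplot2::geom_label(ggplot2::aes(x = 0, y = match(.data$from_module, pm),
                                     label = .data$from_module)) +
    ggplot2::geom_label(ggplot2::aes(x = 1, y = match(.data$to_module, rm_),
                                     label = .data$to_module)) +
    ggplot2::scale_colour_manual(values = c(activating = "#b2182b",
                                            repressive = "#2166ac")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "sign", linewidth = "-log10 adj. p")
}

#' Perturbation-probability histograms per guide
#' @param prob tibble with `sgrna_id` and `prob` (from
#'   [fit_perturbation_model()]).
#' @param bins histogram bins (default 30).
#' @return a ggplot object faceted by guide.
#' @export
plot_perturbation_probability <- function(prob, bins = 30) {
  ggplot2::ggplot(prob, ggplot2::aes(.data$prob)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~sgrna_id, scales = "free_y") +
    ggplot2::labs(x = "perturbation probability", y = "cells") +
    ggplot2::theme_minimal()
}

#' Downsampling sweep curves
#' @param sweep tibble from [cell_number_sweep()] (possibly several
#'   `feature_mode`s row-bound together).
#' @param threshold horizontal reference line (default 0.9).
#' @return a ggplot object.
#' @export
plot_cell_number_sweep <- function(sweep, threshold = 0.9) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$n, .data$median_rho,
                                      colour = .data$feature_mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "cells subsampled", y = "median Spearman vs full",
                  colour = "readout") +
    ggplot2::theme_minimal()
}
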
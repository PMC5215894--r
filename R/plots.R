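#' Plot a flux profile as a pathway-grouped bar chart
#'
#' @param object a `flux_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.flux_fit <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(reaction_id = factor(.data$reaction_id,
                                       levels = .data$reaction_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reaction_id, y = .data$flux,
                                  fill = .data$pathway)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "flux (intensity/min)",
                  title = "Average reaction fluxes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @rdname autoplot.flux_fit
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.exemplar_profile <- function(object, ...) {
  p <- autoplot.flux_fit(object, ...)
  p + ggplot2::labs(title = paste0("Exemplar profile maximizing ",
                                   object$synthesis_id))
}

#' Histogram of sensitivity correlations
#'
#' @param object a `sensitivity_result`.
#' @param binwidth histogram bin width (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_result <- function(object, binwidth = 0.05, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$correlation)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "correlation with original fluxes", y = "count",
                  title = sprintf("Randomized fluxes: %.1f%% correlate > 0.5",
                                  100 * object$fraction_above)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the flux-accumulation correlation matrix
#'
#' Rows and columns follow the stored hierarchical clustering order.
#'
#' @param object a `flux_met_cor`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.flux_met_cor <- function(object, ...) {
  C <- object$correlation
  ro <- rownames(C)[object$row_hclust$order]
  co <- colnames(C)[object$col_hclust$order]
  d <- as_tibble(C, rownames = "reaction_id") |>
    tidyr::pivot_longer(-"reaction_id", names_to = "metabolite_id",
                        values_to = "correlation") |>
    dplyr::mutate(reaction_id = factor(.data$reaction_id, levels = ro),
                  metabolite_id = factor(.data$metabolite_id, levels = co))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metabolite_id,
                                  y = .data$reaction_id,
                                  fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "metabolite accumulation", y = "reaction flux") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Standardized intensity heatmap with clustered sample order
#'
#' @param object a `sample_clustering`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.sample_clustering <- function(object, ...) {
  Z <- object$matrix
  d <- as_tibble(Z, rownames = "metabolite_id") |>
    tidyr::pivot_longer(-"metabolite_id", names_to = "sample_id",
                        values_to = "z") |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = object$order))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id,
                                  y = .data$metabolite_id, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "sample (clustered order)", y = NULL,
                  fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
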
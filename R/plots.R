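# ggplot2 displays for the package's result types.

#' @export
autoplot.frf_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose, y = .data$.pred,
                                       group = .data$sample_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.pred - .data$.pred_sd,
                                      ymax = .data$.pred + .data$.pred_sd),
                         alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µM)", y = "predicted response",
                  title = "Predicted dose-response curves",
                  subtitle = "band: ±1 SD of the per-dose forest distribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.drc_cohort <- function(object, max_curves = 75, ...) {
  long <- tidyr::pivot_longer(object$responses, -"sample_id",
                              names_to = "dose", values_to = "response")
  long$dose <- as.numeric(long$dose)
  keep <- unique(long$sample_id)
  keep <- keep[seq_len(min(length(keep), max_curves))]
  long <- dplyr::filter(long, .data$sample_id %in% keep)
  long <- dplyr::left_join(long, object$truth, by = "sample_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dose, y = .data$response,
                                     group = .data$sample_id,
                                     colour = factor(.data$cluster))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µM)", y = "response",
                  colour = "cluster",
                  title = "Simulated dose-response cohort") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.frf_boot <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "MAE(model A) - MAE(model B)", y = "bootstrap sets",
                  title = "Bootstrap MAE-difference distribution",
                  subtitle = "mass left of 0: model A more accurate") +
    ggplot2::theme_minimal()
}

#' Variable-importance plot
#'
#' Bars of the frequency-based importance of each feature.
#'
#' @param object a fitted [frf()] model.
#' @param top_n show at most this many features (highest first).
#' @return a ggplot object.
#' @export
plot_vim <- function(object, top_n = 25) {
  v <- variable_importance(object) |>
    dplyr::arrange(dplyr::desc(.data$vim)) |>
    dplyr::slice_head(n = top_n)
  ggplot2::ggplot(v, ggplot2::aes(x = stats::reorder(.data$feature, .data$vim),
                                  y = .data$vim)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "selection frequency (selected / picked)",
                  title = "Variable importance") +
    ggplot2::theme_minimal()
}
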
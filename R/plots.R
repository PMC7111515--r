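# ggplot2 views of the main result types.

#' Plot per-state genome coverage
#'
#' @param coverage Tibble from [state_coverage_fractions()], optionally
#'   with a `cell_type` column for faceting.
#' @param drop_quiescent Drop state 0 to show the nonquiescent states on a
#'   readable scale.
#' @return A ggplot.
#' @export
plot_state_coverage <- function(coverage, drop_quiescent = FALSE) {
  df <- coverage
  if (drop_quiescent) df <- filter(df, .data$state != 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$state), y = .data$fraction
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "epigenetic state", y = "genome fraction") +
    ggplot2::theme_minimal()
  if ("cell_type" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~cell_type)
  }
  p
}

#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$to_state), y = factor(.data$from_state),
    fill = log10(.data$count + 1)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(count + 1)") +
    ggplot2::labs(
      x = "state in second cell type", y = "state in first cell type"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meta_profile <- function(object, ...) {
  df <- object$aggregate
  df$position <- (df$position_bin - 0.5) / object$n_position_bins *
    2 * object$window - object$window
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$mean_signal, colour = .data$class
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "distance from interval midpoint (bases)",
      y = "mean signal"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.erp_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$state), y = .data$context, fill = .data$estimate
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", name = "beta"
    ) +
    ggplot2::labs(x = "epigenetic state", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot leave-one-out adjusted r-squared distributions
#'
#' @param loo Tibble from [loo_evaluate()] (possibly several modes bound
#'   together).
#' @return A ggplot: one box per mode (and per category when present).
#' @export
plot_loo <- function(loo) {
  p <- ggplot2::ggplot(loo, ggplot2::aes(
    x = .data$mode, y = .data$adj_r_squared
  )) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "adjusted r² (left-out cell type)") +
    ggplot2::theme_minimal()
  if (length(unique(loo$category)) > 1) {
    p <- p + ggplot2::facet_wrap(~category)
  }
  p
}

#' Plot the expressed-genes vs dynamic-cCREs association
#'
#' @param expressed Tibble with `cell_type`, `n_expressed`.
#' @param dynamic Tibble with `cell_type`, `n`.
#' @param exclude Optional cell types excluded from the fitted line.
#' @return A ggplot scatter with the least-squares line.
#' @export
plot_expression_ccre_association <- function(expressed, dynamic,
                                             exclude = NULL) {
  df <- left_join(
    rename(expressed, n_genes = "n_expressed"),
    rename(dynamic, n_ccres = "n"),
    by = "cell_type"
  )
  fit <- expression_ccre_association(expressed, dynamic, exclude = exclude)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n_ccres, y = .data$n_genes,
    label = .data$cell_type
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::geom_abline(
      intercept = fit$intercept, slope = fit$slope,
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "dynamic cCREs", y = "expressed genes",
      subtitle = paste0("Pearson r = ", round(fit$r, 2))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
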
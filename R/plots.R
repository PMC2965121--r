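# ggplot2 visualisations for the main result types.

#' Map one layer of a soil grid
#'
#' @param grid A `soil_grid`.
#' @param variable Layer to draw (default: first layer).
#' @return A ggplot raster map in plot metres.
#' @export
plot_grid_layer <- function(grid, variable = NULL) {
  if (!inherits(grid, "soil_grid")) abort("`grid` must be a `soil_grid`.")
  variable <- variable %||% grid_variables(grid)[1]
  s <- attr(grid, "cell_size")
  df <- as_tibble(grid)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$cell_i + 0.5) * s, y = (.data$cell_j + 0.5) * s,
    fill = .data[[variable]]
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = variable) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soil_grid <- function(object, variable = NULL, ...) {
  plot_grid_layer(object, variable)
}

#' @export
autoplot.soil_pca <- function(object, k = 3, ...) {
  k <- min(k, length(object$variables))
  df <- tidy.soil_pca(object, "loadings")
  df <- df[df$axis %in% paste0("PCA", seq_len(k)), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$loading, y = .data$variable, fill = .data$loading > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "loading", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phylosoil_signal <- function(object, ...) {
  df <- tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "mean |contrast| under tip shuffling",
      title = sprintf(
        "%s: observed %.3g (p_low = %.3g)",
        object$trait %||% "trait", object$observed, object$p_low
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phylosoil_k <- function(object, ...) {
  if (is.null(object$null)) {
    abort("No null sample: run k_significance() first.")
  }
  df <- tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$K, colour = "red") +
    ggplot2::labs(
      x = "K under tip shuffling",
      title = sprintf(
        "%s: K = %.3g (two-tailed p = %.3g)",
        object$trait %||% "trait", object$K, object$p_two_tailed
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phylosoil_nodes <- function(object, tail = c("high", "low"), ...) {
  tail <- match.arg(tail)
  alpha <- attr(object, "alpha") %||% 0.05
  full <- as_tibble(attr(object, "full") %||% object)
  p_col <- if (tail == "high") "p_high_tip" else "p_low_tip"
  full$p <- full[[p_col]]
  ggplot2::ggplot(full, ggplot2::aes(
    x = .data$n_species, y = .data$p, colour = .data$p <= alpha
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "red", `FALSE` = "grey40"),
      guide = "none"
    ) +
    ggplot2::labs(
      x = "species subtended by node",
      y = sprintf("%s-tail p (tip averaging)", tail),
      title = attr(object, "trait") %||% NULL
    ) +
    ggplot2::theme_minimal()
}
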
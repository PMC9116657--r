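#' Heatmap of a grid weight map
#'
#' Tile plot of per-square weights in excavation orientation (row letters
#' on the vertical axis, first row at the top), the usual way density over
#' an excavation grid is displayed.
#'
#' @param map A [weight_map()].
#' @param trans Transformation for the fill scale (e.g. `"sqrt"` to keep
#'   the periphery visible next to a dominant centre).
#' @return A ggplot object.
#' @export
plot_weight_map <- function(map, trans = "sqrt") {
  stopifnot(inherits(map, "grid_map"))
  ra <- attr(map, "row_alphabet")
  df <- tibble::as_tibble(map)
  df$row <- factor(df$row, levels = rev(ra))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$row,
                                   fill = .data$weight_g)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_viridis_c(name = "g", trans = trans) +
    ggplot2::scale_x_continuous(breaks = seq(1, attr(map, "n_cols"), 2),
                                expand = c(0, 0)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' @rdname plot_weight_map
#' @param object,... `autoplot` arguments (`object` is the map).
#' @method autoplot grid_map
#' @export
autoplot.grid_map <- function(object, ...) plot_weight_map(object, ...)

#' Transect profile plot
#'
#' @param x A [transect()] result.
#' @return A ggplot object (weight per square along the transect).
#' @export
plot_transect <- function(x) {
  stopifnot(all(c("position", "weight_g") %in% names(x)))
  df <- tibble::as_tibble(x)
  df$position <- factor(df$position, levels = df$position)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$weight_g)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "position along transect", y = "weight (g)") +
    ggplot2::theme_minimal()
}

#' Compare hypothesis MNIs graphically
#'
#' @param object A [compare_hypotheses()] result.
#' @param ... Unused.
#' @return A ggplot object: MNI per scenario, annotated with the modelled
#'   mass misfit.
#' @method autoplot budget_comparison
#' @export
autoplot.budget_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mni,
                                   fill = .data$mode)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      ggplot2::aes(label = paste0("MNI ", .data$mni, "\nmisfit ",
                                  round_half_up(.data$misfit_g, 0), " g")),
      vjust = -0.2, size = 3
    ) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, 0.2))) +
    ggplot2::labs(x = NULL, y = "minimum number of individuals",
                  fill = "mode") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20,
                                                       hjust = 1))
}
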
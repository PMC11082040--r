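# ggplot2 visualizations for the package's result types.

#' Plot a tree plot as a stem map
#'
#' Stems drawn at their coordinates, sized by crown radius (or height when
#' crown radii are absent) and colored by dominance class.
#'
#' @param object A [tree_plot()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tree_plot <- function(object, ...) {
  df <- as_tibble(object)
  df$class <- dominance_class(df$height_m)
  size_var <- if (all(is.na(df$crown_radius_m))) "height_m" else
    "crown_radius_m"
  b <- plot_bounds(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_m, .data$y_m)) +
    ggplot2::geom_point(ggplot2::aes(size = .data[[size_var]],
                                     colour = .data$class), alpha = 0.7) +
    ggplot2::coord_equal(xlim = b[c(1, 3)], ylim = b[c(2, 4)]) +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "dominance",
                  size = size_var) +
    ggplot2::theme_minimal()
}

#' Plot a canopy height model
#'
#' @param object A [chm()].
#' @param ... Unused.
#' @return A ggplot raster of canopy heights.
#' @export
autoplot.chm <- function(object, ...) {
  df <- expand.grid(x = chm_cell_x(object), y = chm_cell_y(object))
  df$h <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$h)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (m)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot detection rates by dominance class
#'
#' @param object A [detection_rates()] tibble.
#' @param ... Unused.
#' @return A ggplot of TP/FP/FN rates and F-score per class.
#' @export
autoplot.detection_rates <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("tp_rate", "fp_rate", "fn_rate", "f_score"),
                              names_to = "rate", values_to = "value")
  long$class <- factor(long$class,
                       c("understory", "intermediate", "overstory", "all"))
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$value,
                                     fill = .data$rate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "rate") +
    ggplot2::theme_minimal()
}

#' Plot an opening distribution
#'
#' @param object An [opening_distribution()] tibble.
#' @param ... Unused.
#' @return A ggplot of the proportion of plot area per distance band.
#' @export
autoplot.opening_distribution <- function(object, ...) {
  df <- as_tibble(object)
  df$band <- factor(df$band, levels = df$band)
  ggplot2::ggplot(df, ggplot2::aes(.data$band, .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "distance to nearest tree (m)",
                  y = "proportion of plot area") +
    ggplot2::theme_minimal()
}

#' Map matched, missed, and spurious trees
#'
#' @param match A `match_result`.
#' @param uas,field The tree plots it was computed from.
#' @return A ggplot stem map with match status.
#' @export
plot_matches <- function(match, uas, field) {
  fd <- as_tibble(field)[, c("tree_id", "x_m", "y_m")]
  ud <- as_tibble(uas)[, c("tree_id", "x_m", "y_m")]
  df <- bind_rows(
    mutate(fd[fd$tree_id %in% match$matches$field_id, ], status = "matched"),
    mutate(fd[fd$tree_id %in% match$false_negatives, ],
           status = "false_negative"),
    mutate(ud[ud$tree_id %in% match$false_positives, ],
           status = "false_positive"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_m, .data$y_m,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
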
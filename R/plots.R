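#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a traced cell (xy projection)
#'
#' @param object A `cell_trace`.
#' @param ... Unused.
#' @return A ggplot: trace edges in the xy plane, soma marked.
#' @export
autoplot.cell_trace <- function(object, ...) {
  nd <- object$nodes
  ed <- nd[nd$parent_id != -1L, ]
  pi <- match(ed$parent_id, nd$node_id)
  df <- tibble::tibble(x = nd$x[pi], y = nd$y[pi],
                       xend = ed$x, yend = ed$y)
  soma <- nd[nd$parent_id == -1L, ]
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          linewidth = 0.3) +
    ggplot2::geom_point(data = soma, ggplot2::aes(.data$x, .data$y),
                        colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = object$cell_id) +
    ggplot2::theme_minimal()
}

#' Plot a Sholl profile
#'
#' @param object A `sholl_profile`.
#' @param ... Unused.
#' @return A ggplot of normalized crossings per mm against radius.
#' @export
autoplot.sholl_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(.data$radius, .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "radius (µm)",
                  y = "intersections per mm of arc") +
    ggplot2::theme_minimal()
}

#' Plot a grid-analysis result
#'
#' @param object A `grid_result`.
#' @param ... Unused.
#' @return A ggplot tile map of process length per grid square.
#' @export
autoplot.grid_result <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object$lengths)),
                           j = seq_len(ncol(object$lengths)))
  df$length <- object$lengths[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = .data$length)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "µm / square") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot group means with SEM error bars
#'
#' @param object A `group_anova` from [compare_many()].
#' @param ... Unused.
#' @return A ggplot of group means +/- SEM.
#' @export
autoplot.group_anova <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = object$metric) +
    ggplot2::theme_minimal()
}

#' Plot a density heat map
#'
#' @param map Matrix from [density_heatmap()].
#' @return A ggplot raster of local process density.
#' @export
plot_heatmap <- function(map) {
  df <- tidyr::expand_grid(i = seq_len(nrow(map)), j = seq_len(ncol(map)))
  df$density <- map[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "density") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
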
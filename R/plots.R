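# ggplot2 views: dish occupancy maps, abundance trajectories, score
# series and attractor-basin maps.  Colours follow the model's own
# convention: S cyan, P green, A yellow, B red.

fate_palette <- c(S = "#00c5cd", P = "#2e8b57", A = "#ffd700", B = "#cd2626")

#' @method autoplot dish
#' @export
autoplot.dish <- function(object, ...) {
  df <- tibble(
    row = rep(seq_len(object$height), object$width),
    col = rep(seq_len(object$width), each = object$height),
    occ = as.vector(object$occ),
    valid = as.vector(object$valid)
  )
  df <- df[df$valid, ]
  df$fate <- factor(fate_labels[ifelse(df$occ == 0, NA, df$occ)],
                    levels = fate_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fate)) +
    ggplot2::scale_fill_manual(values = fate_palette, na.value = "grey90",
                               drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "cell") +
    ggplot2::theme_minimal()
}

#' @method autoplot dish_sim
#' @export
autoplot.dish_sim <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$count,
                               colour = .data$cell_type)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = fate_palette) +
    ggplot2::labs(x = "time", y = "cells", colour = "type") +
    ggplot2::theme_minimal()
}

#' @method autoplot score_series
#' @export
autoplot.score_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$normalized)) +
    ggplot2::geom_line(colour = "#2e5aa8") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "pattern similarity") +
    ggplot2::theme_minimal()
}

#' @method autoplot basin_map
#' @export
autoplot.basin_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fate)) +
    ggplot2::geom_point(data = object$attractors, colour = "black",
                        shape = 4, size = 2) +
    ggplot2::scale_fill_manual(values = fate_palette, drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "determinant X", y = "determinant Y",
                  fill = "basin") +
    ggplot2::theme_minimal()
}

#' Plot a dish (occupancy map)
#'
#' @param dish A dish.
#' @return A ggplot.
#' @export
plot_dish <- function(dish) autoplot.dish(dish)
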
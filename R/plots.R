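#' Contour plot of a free-energy landscape
#'
#' Filled landscape with contour lines in 0.5 kcal/mol increments; minima
#' can be overlaid with [find_minima()] output.
#'
#' @param object A [build_fel()] object.
#' @param minima Optional [find_minima()] tibble to overlay.
#' @param contour_step Contour spacing in kcal/mol.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fel <- function(object, minima = NULL, contour_step = 0.5, ...) {
  df <- tidy(object) |> filter(.data$valid)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cv1, y = .data$cv2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$F)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$F),
                          breaks = seq(0, max(df$F) + contour_step,
                                       by = contour_step),
                          colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)") +
    ggplot2::labs(x = sprintf("%s (Å)", object$cv_names[1]),
                  y = sprintf("%s (Å)", object$cv_names[2])) +
    ggplot2::theme_minimal()
  if (!is.null(minima)) {
    p <- p + ggplot2::geom_point(data = minima, colour = "red", shape = 4,
                                 size = 3, stroke = 1.2)
  }
  p
}

#' Heatmap of a residue cross-correlation matrix
#'
#' @param object A [cross_correlation()] object.
#' @param ... Unused.
#' @return A ggplot object (blue = anti-correlated, red = correlated).
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$resid_i, y = .data$resid_j,
                               fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "C") +
    ggplot2::labs(x = "residue", y = "residue") +
    ggplot2::theme_minimal()
}

#' Community diagram with size-proportional circles
#'
#' Communities are laid out on a circle, drawn with radius proportional to
#' the square root of their residue count, and connected by edges whose
#' width is proportional to the cumulative inter-community betweenness.
#'
#' @param object A [community_graph()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.community_graph <- function(object, ...) {
  nd <- object$nodes
  k <- nrow(nd)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  nd$x <- cos(theta)
  nd$y <- sin(theta)
  ed <- object$edges |>
    left_join(nd[, c("community", "x", "y")], by = c(a = "community")) |>
    left_join(nd[, c("community", "x", "y")], by = c(b = "community"),
              suffix = c("", "_end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_end, yend = .data$y_end,
                                       linewidth = .data$weight),
                          colour = "grey50") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size),
                        colour = "steelblue") +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$community)) +
    ggplot2::scale_size_area(max_size = 20, name = "residues") +
    ggplot2::scale_linewidth(range = c(0.3, 3), name = "cumulative\nbetweenness") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Histogram of a pocket volume series
#'
#' @param object A [volume_series()] tibble.
#' @param binwidth Histogram bin width in cubic Angstrom.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.volume_series <- function(object, binwidth = NULL, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$volume)) +
    ggplot2::geom_histogram(binwidth = binwidth, bins = 30,
                            fill = "seagreen", colour = "grey20") +
    ggplot2::labs(x = expression(volume ~ (ring(A)^3)), y = "frames") +
    ggplot2::theme_minimal()
}
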
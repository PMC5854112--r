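#' @export
autoplot.leaf_contour <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(fill = "grey85", colour = "grey25",
                          linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' @export
autoplot.leaf_teeth <- function(object, ...) {
  lm_ <- attr(object, "landmarks")
  p <- autoplot(lm_$contour)
  if (nrow(object) > 0) {
    p <- p +
      ggplot2::geom_point(data = object,
                          ggplot2::aes(x = .data$apex_x, y = .data$apex_y),
                          colour = "#b2182b", size = 1.6) +
      ggplot2::geom_point(data = object,
                          ggplot2::aes(x = .data$sinus_prox_x, y = .data$sinus_prox_y),
                          colour = "#2166ac", size = 1.2, shape = 4) +
      ggplot2::geom_point(data = object,
                          ggplot2::aes(x = .data$sinus_dist_x, y = .data$sinus_dist_y),
                          colour = "#2166ac", size = 1.2, shape = 4)
  }
  p + ggplot2::geom_point(
    data = dplyr::bind_rows(lm_$base, lm_$apex),
    ggplot2::aes(x = .data$x, y = .data$y), colour = "black", size = 2,
    shape = 17)
}

#' Scatter-with-trajectory plot for two genotypes
#'
#' Draws the per-leaf measurement points against blade length together with
#' one local-regression curve per genotype — the standard developmental
#' trajectory layout for dissection index, tooth height, or reporter signal.
#'
#' @param data A data frame with genotype, blade-length and value columns.
#' @param genotype,x,value Column names.
#' @param span,degree Passed to [loess_fit()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(data, genotype = "genotype",
                              x = "blade_length", value = "value",
                              span = 0.75, degree = 1) {
  stopifnot(is.data.frame(data))
  curves <- dplyr::bind_rows(lapply(split(data, data[[genotype]]), function(d) {
    fit <- loess_fit(d, x = x, value = value, span = span, degree = degree)
    cv <- fit$curve[is.finite(fit$curve$fitted), ]
    cv$genotype <- d[[genotype]][1]
    cv
  }))
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data[[x]], y = .data[[value]],
                               colour = .data[[genotype]])) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$grid, y = .data$fitted,
                                    colour = .data$genotype),
                       linewidth = 0.9) +
    ggplot2::labs(x = x, y = value)
}

#' Superimposed mean silhouettes
#'
#' @param silhouettes Named list of mean silhouettes from
#'   [mean_silhouette()].
#' @return A ggplot object.
#' @export
plot_mean_silhouettes <- function(silhouettes) {
  stopifnot(is.list(silhouettes), length(silhouettes) >= 1)
  nm <- names(silhouettes)
  if (is.null(nm)) nm <- paste0("group_", seq_along(silhouettes))
  d <- dplyr::bind_rows(lapply(seq_along(silhouettes), function(i) {
    s <- silhouettes[[i]]
    tibble(x = s$x, y = s$y, group = nm[i])
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$group)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}
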
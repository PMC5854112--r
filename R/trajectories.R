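#' Local-regression (LOESS) trajectory curve
#'
#' Fits a locally weighted polynomial trajectory of a measurement against
#' blade length (the developmental-stage proxy).  At each grid point the
#' `span` fraction of nearest data points is selected, weighted by the
#' tricube kernel of scaled distance, and a polynomial of the given `degree`
#' is fitted and evaluated at the grid point.  Grid points whose local
#' neighbourhood has fewer than `degree + 1` usable points are flagged
#' missing rather than extrapolated.
#'
#' The fit is invariant to data-row order and to duplication of the whole
#' dataset, and a degree-1 fit reproduces exactly linear data exactly.
#'
#' @param data A data frame of one genotype's measurements.
#' @param x,value Column names (strings) of the predictor (default
#'   `"blade_length"`) and response (default `"value"`).
#' @param span Fraction of points in each local window, in (0, 1].
#' @param degree Local polynomial degree, 1 or 2.
#' @param grid Evaluation grid; default `grid_n` equally spaced points over
#'   the data range.
#' @param grid_n Grid size when `grid` is not supplied.
#' @return An object of class `leaf_loess` with a `curve` tibble (`grid`,
#'   `fitted`, `support` = number of points with non-zero weight).
#' @export
loess_fit <- function(data, x = "blade_length", value = "value",
                      span = 0.75, degree = 1, grid = NULL, grid_n = 50) {
  stopifnot(is.data.frame(data))
  if (!x %in% names(data) || !value %in% names(data)) {
    abort(sprintf("`data` must contain columns `%s` and `%s`.", x, value))
  }
  if (!is.numeric(span) || span <= 0 || span > 1) {
    abort("`span` must be in (0, 1].")
  }
  if (!degree %in% c(1, 2)) abort("`degree` must be 1 or 2.")
  xs <- as.numeric(data[[x]])
  ys <- as.numeric(data[[value]])
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  n <- length(xs)
  if (n < degree + 2) abort("not enough points for the requested degree.")
  if (is.null(grid)) grid <- seq(min(xs), max(xs), length.out = grid_n)
  q <- max(degree + 1, ceiling(span * n))

  fitted <- rep(NA_real_, length(grid))
  support <- integer(length(grid))
  for (g in seq_along(grid)) {
    d <- abs(xs - grid[g])
    h <- sort(d, partial = q)[q]
    if (h == 0) h <- max(d[d > 0][1], .Machine$double.eps)
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    support[g] <- sum(use)
    if (sum(use) < degree + 1 || length(unique(xs[use])) < degree + 1) next
    X <- outer(xs[use] - grid[g], 0:degree, "^")
    fit <- lm.wfit(X, ys[use], w[use])
    fitted[g] <- fit$coefficients[1]
  }
  structure(list(
    curve = tibble(grid = grid, fitted = fitted, support = support),
    span = span, degree = degree, n = n,
    data = tibble(x = xs, y = ys), x_name = x, value_name = value
  ), class = "leaf_loess")
}

#' @export
print.leaf_loess <- function(x, ...) {
  cat(sprintf("<leaf_loess: degree %d, span %.2f, n = %d, %d grid points (%d fitted)>\n",
              x$degree, x$span, x$n, nrow(x$curve), sum(is.finite(x$curve$fitted))))
  invisible(x)
}

#' @export
tidy.leaf_loess <- function(x, ...) x$curve

#' @export
glance.leaf_loess <- function(x, ...) {
  pred <- predict_loess(x, x$data$x)
  rss <- sum((x$data$y - pred)^2, na.rm = TRUE)
  tibble(n = x$n, span = x$span, degree = x$degree,
         rmse = sqrt(rss / sum(is.finite(pred))))
}

# evaluate the local fit at arbitrary x values
predict_loess <- function(object, newx) {
  refit <- loess_fit(tibble(x = object$data$x, y = object$data$y),
                     x = "x", value = "y", span = object$span,
                     degree = object$degree, grid = newx)
  refit$curve$fitted
}

#' @export
autoplot.leaf_loess <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = object$curve[is.finite(object$curve$fitted), ],
                       ggplot2::aes(x = .data$grid, y = .data$fitted),
                       colour = "#b2182b", linewidth = 0.8) +
    ggplot2::labs(x = object$x_name, y = object$value_name)
}

#' Blade-length-class comparisons between two genotypes
#'
#' Assigns measurements to half-open blade-length classes `[e_i, e_{i+1})`
#' and runs an equal-variance two-sample Student's t-test per class.  The
#' defaults (200-400, 400-600, 600-800 micrometres) are the early
#' developmental window in which reporter-signal trajectories are compared.
#' Classes with fewer than 2 points in either genotype are reported as
#' untestable rather than dropped.  No multiple-testing correction is
#' applied across classes by default (`p_adjust = "none"`).
#'
#' @param data A data frame with a genotype column (exactly 2 levels), a
#'   blade-length column, and a value column.
#' @param class_edges Increasing vector of class boundaries, micrometres.
#' @param genotype,x,value Column names.
#' @param var_equal Use the pooled-variance Student's t-test (default); set
#'   `FALSE` for Welch.
#' @param p_adjust Multiple-testing correction method across classes, passed
#'   to [stats::p.adjust()]; `"none"` by default.
#' @return A tibble with one row per class: `class_lo`, `class_hi`, `n_A`,
#'   `n_B`, `mean_A`, `mean_B`, `t`, `p`, `testable`.  Group A is the first
#'   factor level (alphabetical for character genotypes).
#' @export
bin_and_test <- function(data, class_edges = c(200, 400, 600, 800),
                         genotype = "genotype", x = "blade_length",
                         value = "value", var_equal = TRUE,
                         p_adjust = "none") {
  stopifnot(is.data.frame(data))
  for (col in c(genotype, x, value)) {
    if (!col %in% names(data)) abort(sprintf("missing column `%s`.", col))
  }
  if (length(class_edges) < 2 || any(diff(class_edges) <= 0)) {
    abort("`class_edges` must be increasing with at least 2 values.")
  }
  g <- factor(data[[genotype]])
  if (nlevels(g) != 2) abort("`data` must contain exactly 2 genotypes.")
  lv <- levels(g)
  xs <- as.numeric(data[[x]])
  vs <- as.numeric(data[[value]])
  rows <- lapply(seq_len(length(class_edges) - 1), function(k) {
    lo <- class_edges[k]; hi <- class_edges[k + 1]
    in_class <- xs >= lo & xs < hi
    a <- vs[in_class & g == lv[1]]
    b <- vs[in_class & g == lv[2]]
    testable <- length(a) >= 2 && length(b) >= 2
    if (testable) {
      tt <- stats::t.test(a, b, var.equal = var_equal)
      tibble(class_lo = lo, class_hi = hi, n_A = length(a), n_B = length(b),
             mean_A = mean(a), mean_B = mean(b),
             t = unname(tt$statistic), p = tt$p.value, testable = TRUE)
    } else {
      tibble(class_lo = lo, class_hi = hi, n_A = length(a), n_B = length(b),
             mean_A = if (length(a)) mean(a) else NA_real_,
             mean_B = if (length(b)) mean(b) else NA_real_,
             t = NA_real_, p = NA_real_, testable = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  attr(out, "groups") <- lv
  out
}

#' Phenotype frequency table
#'
#' Converts per-genotype phenotype counts (e.g. cotyledon-fusion classes)
#' into within-genotype frequencies.
#'
#' @param counts A data frame with columns `genotype`, `category`, `count`.
#' @return A tibble with an added `frequency` column; frequencies sum to 1
#'   within each genotype.
#' @export
phenotype_frequencies <- function(counts) {
  stopifnot(is.data.frame(counts))
  for (col in c("genotype", "category", "count")) {
    if (!col %in% names(counts)) abort(sprintf("missing column `%s`.", col))
  }
  if (any(counts$count < 0)) abort("counts must be non-negative.")
  totals <- tapply(counts$count, counts$genotype, sum)
  if (any(totals == 0)) {
    abort(sprintf("genotype `%s` has zero total count.",
                  names(totals)[which(totals == 0)[1]]))
  }
  dplyr::mutate(dplyr::group_by(as_tibble(counts), .data$genotype),
                frequency = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}
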
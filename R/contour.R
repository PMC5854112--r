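#' Leaf contours
#'
#' A leaf contour is a closed, simple, counter-clockwise polyline in physical
#' units (micrometres).  It is stored as a tibble with columns `x` and `y`;
#' the closing edge from the last vertex back to the first is implicit, so the
#' first vertex is never repeated at the end.  All shape statistics in the
#' package (area, perimeter, dissection index, landmarks) consume this
#' representation.
#'
#' `as_leaf_contour()` accepts any data frame with `x`/`y` (or `x_um`/`y_um`)
#' columns or a two-column matrix, drops a repeated closing vertex, and
#' re-orients the polygon counter-clockwise so that its shoelace area is
#' positive.
#'
#' @param x A data frame with columns `x` and `y` (micrometres), a data frame
#'   with `x_um`/`y_um`, or a numeric matrix with two columns.
#' @param pixel_size Optional pixel size (micrometres per pixel) recording the
#'   raster the contour came from; purely provenance.
#'
#' @return A `leaf_contour` tibble with columns `x` and `y`.
#' @examples
#' sq <- as_leaf_contour(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' polygon_area(sq)
#' polygon_perimeter(sq)
#' @export
as_leaf_contour <- function(x, pixel_size = NULL) {
  if (is.matrix(x)) {
    x <- as.data.frame(x)
    names(x) <- c("x", "y")
  }
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame or a two-column matrix.")
  }
  if (all(c("x_um", "y_um") %in% names(x))) {
    x <- data.frame(x = x$x_um, y = x$y_um)
  }
  if (!all(c("x", "y") %in% names(x))) {
    abort("contour needs `x`/`y` (or `x_um`/`y_um`) columns.")
  }
  xs <- as.numeric(x$x)
  ys <- as.numeric(x$y)
  v <- tibble(x = xs, y = ys)
  if (anyNA(v$x) || anyNA(v$y)) abort("contour coordinates contain NA.")
  n <- nrow(v)
  if (n >= 4 && v$x[1] == v$x[n] && v$y[1] == v$y[n]) {
    v <- v[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n < 3) abort("a contour needs at least 3 vertices.")
  a <- shoelace_area(v$x, v$y)
  if (a == 0) abort("degenerate contour: zero shoelace area.")
  if (a < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  new_leaf_contour(v, pixel_size = pixel_size)
}

new_leaf_contour <- function(v, pixel_size = NULL) {
  out <- as_tibble(v)
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("leaf_contour", class(tibble()))
  out
}

#' @export
print.leaf_contour <- function(x, ...) {
  cat(sprintf("<leaf_contour: %d vertices, area %.4g, perimeter %.4g>\n",
              nrow(x), polygon_area(x), polygon_perimeter(x)))
  NextMethod()
}

# signed shoelace area (positive = counter-clockwise)
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

check_contour <- function(c, arg = "c") {
  if (!is.data.frame(c) || !all(c("x", "y") %in% names(c))) {
    abort(sprintf("`%s` must be a contour data frame with `x` and `y`.", arg))
  }
  if (nrow(c) < 3) abort(sprintf("`%s` has fewer than 3 vertices.", arg))
  invisible(c)
}

#' Polygon area and perimeter
#'
#' Shoelace area and closed perimeter of a contour.  The area of a
#' counter-clockwise contour is positive; `as_leaf_contour()` enforces that
#' orientation, and `polygon_area()` returns the absolute value so that the
#' result is usable on raw vertex tables as well.
#'
#' @param c A contour (see [as_leaf_contour()]).
#' @return Area in squared micrometres, or perimeter in micrometres.
#' @export
polygon_area <- function(c) {
  check_contour(c)
  abs(shoelace_area(c$x, c$y))
}

#' @rdname polygon_area
#' @export
polygon_perimeter <- function(c) {
  check_contour(c)
  n <- nrow(c)
  j <- c(2:n, 1)
  sum(sqrt((c$x[j] - c$x)^2 + (c$y[j] - c$y)^2))
}

# cumulative arclength at each vertex (first vertex = 0), plus total length
arclength_param <- function(c) {
  n <- nrow(c)
  j <- c(2:n, 1)
  seg <- sqrt((c$x[j] - c$x)^2 + (c$y[j] - c$y)^2)
  list(s = c(0, cumsum(seg))[seq_len(n)], total = sum(seg), seg = seg)
}

# linear interpolation along the closed contour at arclengths `at`
interp_contour <- function(c, at) {
  n <- nrow(c)
  p <- arclength_param(c)
  s <- c(p$s, p$total)
  xs <- c(c$x, c$x[1])
  ys <- c(c$y, c$y[1])
  at <- at %% p$total
  xi <- stats::approx(s, xs, xout = at, ties = "ordered")$y
  yi <- stats::approx(s, ys, xout = at, ties = "ordered")$y
  tibble(x = xi, y = yi)
}

#' Resample a contour to uniform arclength spacing
#'
#' Places `n` vertices equally spaced in arclength along the closed contour,
#' starting at the original first vertex, preserving orientation.  Uniform
#' spacing is a precondition for [curvature_profile()].
#'
#' @param c A contour.
#' @param n Number of vertices (at least 16).
#' @param offset Arclength (micrometres) at which the first output vertex is
#'   placed; used e.g. to start a resampled contour at a landmark.
#' @return A `leaf_contour` with `n` vertices.
#' @export
resample_contour <- function(c, n = 1024, offset = 0) {
  check_contour(c)
  if (!is.numeric(n) || length(n) != 1 || n < 16) {
    abort("`n` must be a single number >= 16.")
  }
  n <- as.integer(n)
  total <- arclength_param(c)$total
  at <- offset + total * (seq_len(n) - 1) / n
  out <- interp_contour(c, at)
  out <- new_leaf_contour(out, pixel_size = attr(c, "pixel_size"))
  # vertices are equally spaced along the source polyline; chords across
  # corners may be slightly shorter, so record the certified spacing
  attr(out, "uniform_spacing") <- TRUE
  out
}

#' Smooth a contour with a periodic Gaussian kernel
#'
#' Smooths the x and y coordinate sequences with a Gaussian kernel whose
#' standard deviation `sigma` is expressed in arclength (micrometres), using
#' periodic (wrap-around) boundary conditions.  `sigma = 0` returns the
#' contour unchanged.
#'
#' @param c A contour.
#' @param sigma Kernel standard deviation in micrometres of arclength.
#' @return A `leaf_contour` with the same number of vertices.
#' @export
smooth_contour <- function(c, sigma) {
  check_contour(c)
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    abort("`sigma` must be a single non-negative number.")
  }
  if (sigma == 0) return(as_leaf_contour(c, pixel_size = attr(c, "pixel_size")))
  p <- arclength_param(c)
  xs <- gauss_smooth_periodic(c$x, p$s, p$total, sigma)
  ys <- gauss_smooth_periodic(c$y, p$s, p$total, sigma)
  as_leaf_contour(data.frame(x = xs, y = ys),
                  pixel_size = attr(c, "pixel_size"))
}

# periodic Gaussian smoothing of values sampled at arclengths s on [0, total)
gauss_smooth_periodic <- function(v, s, total, sigma) {
  d <- abs(outer(s, s, "-"))
  d <- pmin(d, total - d)
  w <- exp(-d^2 / (2 * sigma^2))
  as.numeric((w %*% v) / rowSums(w))
}

#' Signed curvature along a uniformly resampled contour
#'
#' Computes the discrete signed curvature as the arclength derivative of the
#' periodically smoothed tangent angle.  On a counter-clockwise contour the
#' sign convention is positive where the boundary is locally convex (bulging
#' outward) and negative in concavities such as sinuses and the petiole
#' junction.  The tangent angle is unwrapped, its linear winding ramp removed,
#' the periodic residual smoothed with a Gaussian of standard deviation
#' `sigma` (arclength micrometres), and the ramp restored, so that the
#' curvature integrates to exactly one full turn.
#'
#' @param c A contour with uniform vertex spacing (see [resample_contour()];
#'   spacing deviations beyond 1% raise an error).
#' @param sigma Smoothing scale in micrometres; default `perimeter / 200`.
#' @return A `curvature_profile` tibble with columns `arclength` (micrometres,
#'   cumulative from vertex 1) and `kappa` (1/micrometres), one row per
#'   contour vertex.
#' @export
curvature_profile <- function(c, sigma = NULL) {
  check_contour(c)
  p <- arclength_param(c)
  n <- nrow(c)
  h <- p$total / n
  if (!isTRUE(attr(c, "uniform_spacing")) &&
      max(abs(p$seg - h)) > 0.01 * h) {
    abort(paste0("contour is not uniformly spaced (deviation > 1%); ",
                 "resample with resample_contour() first."))
  }
  if (is.null(sigma)) sigma <- p$total / 200
  # tangent angle from central differences
  ip <- c(2:n, 1)
  im <- c(n, 1:(n - 1))
  tx <- c$x[ip] - c$x[im]
  ty <- c$y[ip] - c$y[im]
  theta <- atan2(ty, tx)
  # unwrap
  dth <- diff(theta)
  dth <- dth - 2 * pi * round(dth / (2 * pi))
  theta_u <- theta[1] + c(0, cumsum(dth))
  # remove the winding ramp (one full turn for a simple CCW contour)
  ramp <- 2 * pi * (seq_len(n) - 1) / n
  resid <- theta_u - ramp
  if (sigma > 0) resid <- gauss_smooth_fft(resid, h, sigma)
  theta_s <- resid + ramp
  # kappa = d theta / d s, central differences with periodic ramp closure
  dth2 <- theta_s[ip] - theta_s[im]
  dth2[1] <- dth2[1] + 2 * pi
  dth2[n] <- dth2[n] + 2 * pi
  kappa <- dth2 / (2 * h)
  out <- tibble(arclength = p$s, kappa = kappa)
  class(out) <- c("curvature_profile", class(tibble()))
  attr(out, "total_length") <- p$total
  attr(out, "sigma") <- sigma
  out
}

# fast periodic Gaussian smoothing for uniformly spaced samples (spacing h)
gauss_smooth_fft <- function(v, h, sigma) {
  n <- length(v)
  half <- floor(n / 2)
  lag <- c(0:half, -(n - half - 1):-1)[seq_len(n)]
  k <- exp(-(lag * h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(v) * Conj(stats::fft(k)), inverse = TRUE)) / n
}

#' Read and write contour CSV files
#'
#' The on-disk contour dialect is a CSV with header `x_um,y_um`, vertices in
#' counter-clockwise order and the first vertex not repeated at the end.
#'
#' @param path File path.
#' @param c A contour.
#' @return `read_contour_csv()` returns a `leaf_contour`;
#'   `write_contour_csv()` returns `path` invisibly.
#' @export
read_contour_csv <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    x_um = readr::col_double(), y_um = readr::col_double()
  ))
  as_leaf_contour(d)
}

#' @rdname read_contour_csv
#' @export
write_contour_csv <- function(c, path) {
  check_contour(c)
  c <- as_leaf_contour(c)
  readr::write_csv(tibble(x_um = c$x, y_um = c$y), path)
  invisible(path)
}

# does the closed polyline self-intersect? (segment pair test, chunked)
contour_is_simple <- function(c, chunk = 256L) {
  n <- nrow(c)
  j <- c(2:n, 1)
  x1 <- c$x; y1 <- c$y; x2 <- c$x[j]; y2 <- c$y[j]
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    # candidate partners: all later segments, excluding neighbours
    for (i in idx) {
      if (i + 2L > n) next
      ks <- (i + 2L):n
      if (i == 1L) ks <- ks[ks != n]  # closing edge adjoins the first
      if (length(ks) == 0) next
      # bounding-box prefilter
      keep <- pmax(x1[ks], x2[ks]) >= min(x1[i], x2[i]) &
              pmin(x1[ks], x2[ks]) <= max(x1[i], x2[i]) &
              pmax(y1[ks], y2[ks]) >= min(y1[i], y2[i]) &
              pmin(y1[ks], y2[ks]) <= max(y1[i], y2[i])
      ks <- ks[keep]
      if (length(ks) == 0) next
      if (any(segments_cross(x1[i], y1[i], x2[i], y2[i],
                             x1[ks], y1[ks], x2[ks], y2[ks]))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# vectorized proper-intersection test of segment (a,b) against segments (c,d)
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}
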
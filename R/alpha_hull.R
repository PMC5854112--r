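#' Alpha-shape of a planar point set
#'
#' Computes the alpha-generalized hull of a point set as the alpha-shape: the
#' points are Delaunay-triangulated and triangles whose circumradius exceeds
#' `alpha` are discarded.  The hull area is the total area of the kept
#' triangles, the boundary is the set of edges belonging to exactly one kept
#' triangle stitched into closed loops, and the perimeter is the total
#' boundary length.  As `alpha` grows the result converges to the convex
#' hull; as it shrinks the hull follows finer features, until no triangle
#' survives and an error is raised.
#'
#' The alpha-shape (segment-bounded) is used as the computable realization of
#' the arc-bounded alpha-hull; in the dense-sampling regime the pipeline
#' operates in, their perimeters and areas agree to within the sampling
#' resolution.  Near-degenerate triangles whose circumradius overflows are
#' treated as circumradius infinity and dropped unless `alpha = Inf`.
#'
#' @param points A contour, data frame with `x`/`y`, or two-column matrix of
#'   points (micrometres).  At least 3 non-collinear points.
#' @param alpha Radius parameter in micrometres (> 0; may be `Inf` for the
#'   convex hull).
#' @return An object of class `alpha_hull`: a list with `alpha`, `area`,
#'   `perimeter`, `boundary` (list of closed-loop tibbles with `x`, `y`),
#'   `source_n`, and `triangles` (index matrix of kept triangles).
#' @examples
#' sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' h <- alpha_shape(sq, alpha = 10)
#' h$area       # 1
#' h$perimeter  # 4
#' @export
alpha_shape <- function(points, alpha) {
  if (is.matrix(points)) points <- data.frame(x = points[, 1], y = points[, 2])
  if (!all(c("x", "y") %in% names(points))) {
    abort("`points` must have `x` and `y` columns.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive number (or Inf).")
  }
  P <- unique(cbind(as.numeric(points$x), as.numeric(points$y)))
  n <- nrow(P)
  if (n < 3) abort("need at least 3 distinct points.")
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  sv <- svd(Q, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-12 * sv[1]) abort("all points are collinear.")

  tri <- delaunay_triangulate(P)
  r <- triangle_circumradius(P, tri)
  a <- triangle_area(P, tri)
  # near-collinear triangles: circumradius treated as infinite
  r[!is.finite(r)] <- Inf
  keep <- if (is.infinite(alpha)) rep(TRUE, length(r)) else r <= alpha
  if (!any(keep)) {
    abort(sprintf(
      "alpha = %g is below the feature scale: minimal triangle circumradius is %g.",
      alpha, min(r)))
  }
  kt <- tri[keep, , drop = FALSE]
  hull_area <- sum(a[keep])
  bnd <- boundary_loops(P, kt)
  perim <- sum(vapply(bnd, function(L) {
    n_ <- nrow(L); j <- c(2:n_, 1)
    sum(sqrt((L$x[j] - L$x)^2 + (L$y[j] - L$y)^2))
  }, numeric(1)))
  structure(list(alpha = alpha, area = hull_area, perimeter = perim,
                 boundary = bnd, source_n = n, triangles = kt,
                 points = tibble(x = P[, 1], y = P[, 2])),
            class = "alpha_hull")
}

#' @export
print.alpha_hull <- function(x, ...) {
  cat(sprintf(
    "<alpha_hull: alpha %.4g, area %.6g, perimeter %.6g, %d boundary loop(s), %d points>\n",
    x$alpha, x$area, x$perimeter, length(x$boundary), x$source_n))
  invisible(x)
}

#' @export
tidy.alpha_hull <- function(x, ...) {
  tibble(alpha = x$alpha, area = x$area, perimeter = x$perimeter,
         n_loops = length(x$boundary), source_n = x$source_n)
}

#' @export
autoplot.alpha_hull <- function(object, ...) {
  pts <- object$points
  loops <- dplyr::bind_rows(
    purrr::imap(object$boundary, ~ dplyr::mutate(.x, loop = .y)))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.3, colour = "grey55") +
    ggplot2::geom_polygon(data = loops,
                          ggplot2::aes(group = .data$loop),
                          fill = NA, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("alpha-shape, alpha = %.3g", object$alpha))
}

# Delaunay triangulation with a deterministic symbolic-perturbation jitter to
# break cocircular degeneracies; triangle geometry downstream always uses the
# original coordinates.
delaunay_triangulate <- function(P) {
  n <- nrow(P)
  diag_ <- sqrt(sum((apply(P, 2, max) - apply(P, 2, min))^2))
  # deterministic per-index jitter (multiplicative congruential hash)
  h1 <- (seq_len(n) * 2654435761) %% 2^16 / 2^16 - 0.5
  h2 <- (seq_len(n) * 1013904223) %% 2^16 / 2^16 - 0.5
  eps <- 1e-10 * diag_
  # deterministic shuffled insertion order: consecutive boundary points
  # produce degenerate insertion cavities
  ord <- order(h1)
  tri <- .delaunay_cpp(P[ord, 1] + eps * h1[ord], P[ord, 2] + eps * h2[ord])
  if (nrow(tri) == 0) abort("triangulation failed (degenerate point set).")
  tri[] <- ord[tri]
  tri
}

triangle_circumradius <- function(P, tri) {
  ax <- P[tri[, 1], 1]; ay <- P[tri[, 1], 2]
  bx <- P[tri[, 2], 1]; by <- P[tri[, 2], 2]
  cx <- P[tri[, 3], 1]; cy <- P[tri[, 3], 2]
  la <- sqrt((bx - cx)^2 + (by - cy)^2)
  lb <- sqrt((ax - cx)^2 + (ay - cy)^2)
  lc <- sqrt((ax - bx)^2 + (ay - by)^2)
  K <- abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
  out <- rep(Inf, nrow(tri))
  pos <- K > 0
  out[pos] <- (la * lb * lc)[pos] / (4 * K[pos])
  out
}

triangle_area <- function(P, tri) {
  ax <- P[tri[, 1], 1]; ay <- P[tri[, 1], 2]
  bx <- P[tri[, 2], 1]; by <- P[tri[, 2], 2]
  cx <- P[tri[, 3], 1]; cy <- P[tri[, 3], 2]
  abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
}

# stitch the once-used edges of the kept triangles into closed loops
boundary_loops <- function(P, tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  N <- nrow(P) + 1
  key <- pmin(e[, 1], e[, 2]) * N + pmax(e[, 1], e[, 2])
  ord <- order(key)
  ks <- key[ord]
  first <- !duplicated(ks)
  cnt <- tabulate(cumsum(first))
  once_keys <- ks[first][cnt == 1]
  sel <- key %in% once_keys
  eb <- e[sel, , drop = FALSE]
  if (nrow(eb) == 0) return(list())
  loops <- list()
  used <- logical(nrow(eb))
  # adjacency: from -> row
  repeat {
    start <- which(!used)[1]
    if (is.na(start)) break
    chain <- eb[start, 1]
    cur <- eb[start, 2]
    used[start] <- TRUE
    repeat {
      chain <- c(chain, cur)
      cand <- which(!used & (eb[, 1] == cur | eb[, 2] == cur))
      if (length(cand) == 0) break
      k <- cand[1]
      used[k] <- TRUE
      cur <- if (eb[k, 1] == cur) eb[k, 2] else eb[k, 1]
      if (cur == chain[1]) break
    }
    loops[[length(loops) + 1L]] <- tibble(x = P[chain, 1], y = P[chain, 2])
  }
  # largest loop first
  areas <- vapply(loops, function(L) abs(shoelace_area(L$x, L$y)), numeric(1))
  loops[order(-areas)]
}

#' Default alpha for a contour
#'
#' Heuristic radius parameter for [alpha_shape()] on a leaf contour:
#' `0.2 * the bounding-box diagonal`.  Chosen so that the hull bridges
#' sinuses between marginal teeth while still following the global blade
#' outline and the petiole; always overridable wherever an `alpha` argument
#' is accepted.
#'
#' @param c A contour.
#' @return Alpha in micrometres.
#' @export
select_alpha <- function(c) {
  check_contour(c)
  0.2 * sqrt(diff(range(c$x))^2 + diff(range(c$y))^2)
}
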
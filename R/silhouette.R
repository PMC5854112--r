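#' Rigidly align contours on their base-apex axis
#'
#' Resamples each contour to `n_points` vertices starting at its base
#' landmark, then applies the rigid motion (translation + rotation, never
#' scaling) that puts the base at the origin and the base-to-apex axis along
#' +y.  Size differences between leaves are deliberately preserved.
#'
#' @param contours A list of contours, or a cohort tibble with a `contour`
#'   list-column.
#' @param n_points Vertices per aligned contour.
#' @return A list: `aligned` (list of `leaf_contour`s), `transforms` (per
#'   leaf: rotation matrix `R` and translation such that
#'   `aligned = (xy - base) %*% t(R)`).
#' @export
align_contours <- function(contours, n_points = 512) {
  if (is.data.frame(contours) && "contour" %in% names(contours)) {
    contours <- contours$contour
  }
  stopifnot(is.list(contours), length(contours) >= 1)
  aligned <- vector("list", length(contours))
  transforms <- vector("list", length(contours))
  for (i in seq_along(contours)) {
    c_ <- contours[[i]]
    lm_ <- tryCatch(find_base_and_apex(c_, n_points = max(n_points, 256)),
                    error = function(e) {
      abort(sprintf("landmark detection failed on leaf %d: %s", i,
                    conditionMessage(e)))
    })
    rc <- lm_$contour
    # start exactly at the foot of the base point on the contour, so that
    # corresponding vertices of mirror-image leaves coincide exactly
    off <- project_arclength(rc, c(lm_$base$x, lm_$base$y))
    rs <- resample_contour(rc, n_points, offset = off)
    base <- c(lm_$base$x, lm_$base$y)
    ax <- c(lm_$apex$x, lm_$apex$y) - base
    ax <- ax / sqrt(sum(ax^2))
    # rotation sending ax to (0, 1)
    R <- rbind(c(ax[2], -ax[1]), c(ax[1], ax[2]))
    xy <- sweep(cbind(rs$x, rs$y), 2, base) %*% t(R)
    aligned[[i]] <- new_leaf_contour(tibble(x = xy[, 1], y = xy[, 2]))
    transforms[[i]] <- list(R = R, base = base)
  }
  list(aligned = aligned, transforms = transforms)
}

#' Mean silhouette of a set of leaves
#'
#' Pointwise average of landmark-aligned, arclength-resampled contours: each
#' leaf is resampled to `n_points` starting at its base, rigidly aligned
#' base-to-apex upward (no scaling, so genotype size differences survive
#' averaging), and vertex `i` of the result is the mean of vertex `i` across
#' leaves.
#'
#' @inheritParams align_contours
#' @return A `leaf_contour` with `n_points` vertices, with attribute
#'   `n_leaves`.
#' @export
mean_silhouette <- function(contours, n_points = 512) {
  al <- align_contours(contours, n_points = n_points)
  X <- sapply(al$aligned, function(a) a$x)
  Y <- sapply(al$aligned, function(a) a$y)
  if (is.null(dim(X))) { X <- matrix(X, ncol = 1); Y <- matrix(Y, ncol = 1) }
  out <- as_leaf_contour(data.frame(x = rowMeans(X), y = rowMeans(Y)))
  attr(out, "n_leaves") <- ncol(X)
  out
}

# arclength of the closest point on the contour polyline to `p`
project_arclength <- function(c, p) {
  n <- nrow(c)
  j <- c(2:n, 1)
  ex <- c$x[j] - c$x
  ey <- c$y[j] - c$y
  len2 <- ex^2 + ey^2
  t <- ((p[1] - c$x) * ex + (p[2] - c$y) * ey) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  qx <- c$x + t * ex
  qy <- c$y + t * ey
  d2 <- (qx - p[1])^2 + (qy - p[2])^2
  k <- which.min(d2)
  par_ <- arclength_param(c)
  par_$s[k] + t[k] * sqrt(len2[k])
}

#' Compare two mean silhouettes
#'
#' Superimposes two mean silhouettes (vertex-by-vertex, both produced with
#' the same `n_points`) and reports the pointwise distance profile — the
#' computational analogue of overlaying genotype mean shapes to locate where
#' margins diverge (typically at sinuses when serration is lost).
#'
#' @param a,b Mean silhouettes from [mean_silhouette()] with equal vertex
#'   counts.
#' @return A tibble with `index`, `x`, `y` (midpoint of the vertex pair) and
#'   `distance` (micrometres).
#' @export
silhouette_difference <- function(a, b) {
  check_contour(a); check_contour(b)
  if (nrow(a) != nrow(b)) abort("mean silhouettes must have equal vertex counts.")
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  tibble(index = seq_len(nrow(a)),
         x = (a$x + b$x) / 2, y = (a$y + b$y) / 2,
         distance = d)
}
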
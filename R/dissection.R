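#' Isoperimetric shape dissection
#'
#' `shape_di()` is the raw isoperimetric quotient `perimeter^2 / (4 * pi *
#' area)`: 1 for a circle (the isoperimetric identity) and larger for any
#' other shape, growing with boundary complexity.
#'
#' @param perimeter Perimeter(s), micrometres (> 0).
#' @param area Area(s), squared micrometres (> 0).
#' @return Dimensionless dissection value(s).
#' @examples
#' shape_di(2 * pi, pi)  # circle: 1
#' shape_di(4, 1)        # unit square: 4 / pi
#' @export
shape_di <- function(perimeter, area) {
  if (!is.numeric(perimeter) || !is.numeric(area)) {
    abort("`perimeter` and `area` must be numeric.")
  }
  if (any(!is.finite(perimeter)) || any(!is.finite(area)) ||
      any(perimeter <= 0) || any(area <= 0)) {
    abort("`perimeter` and `area` must be positive and finite.")
  }
  perimeter^2 / (4 * pi * area)
}

#' Alpha-hull-normalized dissection index of a leaf contour
#'
#' Computes the full dissection record of a leaf: the raw isoperimetric
#' dissection of the contour (`leaf_DI`), the same quantity for the contour's
#' alpha-hull (`ahull_DI`), and their ratio `DI = leaf_DI / ahull_DI` — the
#' final, scale-free statistic compared across genotypes.  The alpha-hull
#' normalization removes the contribution of overall blade shape (elongation,
#' petiole) so that `DI` is close to 1 for a smooth-margined leaf and grows
#' with marginal dissection.
#'
#' The hull is computed on the contour resampled to `n_points` vertices, so
#' hull resolution is decoupled from pixel size.  Contours are measured with
#' the petiole attached: the hull is meant to wrap the serrations and the
#' petiole alike.
#'
#' @param c A contour (petiole included, if present).
#' @param alpha `"auto"` (default, [select_alpha()]) or a radius in
#'   micrometres.
#' @param n_points Number of resampled contour vertices fed to the hull.
#' @param genotype,leaf_rank,leaf_id Optional metadata carried into the
#'   output row.
#' @param blade_length Optional blade length (micrometres) carried into the
#'   output row (e.g. from [find_base_and_apex()]).
#' @return A one-row tibble with `leaf_DI`, `ahull_DI`, `DI`, `leaf_area`,
#'   `leaf_perimeter`, `ahull_area`, `ahull_perimeter`, `alpha`, plus any
#'   metadata supplied.
#' @export
leaf_di <- function(c, alpha = "auto", n_points = 1024,
                    genotype = NA_character_, leaf_rank = NA_character_,
                    leaf_id = NA_character_, blade_length = NA_real_) {
  check_contour(c)
  rc <- resample_contour(c, n_points)
  if (identical(alpha, "auto")) alpha <- select_alpha(rc)
  hull <- alpha_shape(rc, alpha)
  la <- polygon_area(c)
  lp <- polygon_perimeter(c)
  leaf_DI <- shape_di(lp, la)
  ahull_DI <- shape_di(hull$perimeter, hull$area)
  tibble(
    leaf_id = leaf_id, genotype = genotype, leaf_rank = leaf_rank,
    blade_length = blade_length,
    leaf_DI = leaf_DI, ahull_DI = ahull_DI, DI = leaf_DI / ahull_DI,
    leaf_area = la, leaf_perimeter = lp,
    ahull_area = hull$area, ahull_perimeter = hull$perimeter,
    alpha = alpha
  )
}

#' Measure a cohort of leaves
#'
#' Applies [leaf_di()] and the landmark measurements to every leaf of a
#' cohort tibble (as produced by [generate_cohort()], or any tibble with a
#' `contour` list-column and metadata columns), returning one tidy row per
#' leaf: dissection record, measured blade length, tooth count, and the
#' height of the first (most basal) tooth.
#'
#' @param cohort A tibble with a `contour` list-column; columns `leaf_id` and
#'   `genotype` are carried through when present.
#' @param alpha `"auto"` or micrometres, passed to [leaf_di()].
#' @param n_points Contour resampling used for hull and landmarks.
#' @param ... Passed to [detect_teeth()] (e.g. `min_prominence`,
#'   `min_height`).
#' @return A tibble with one row per leaf.
#' @export
measure_cohort <- function(cohort, alpha = "auto", n_points = 1024, ...) {
  stopifnot(is.data.frame(cohort), "contour" %in% names(cohort))
  ids <- if ("leaf_id" %in% names(cohort)) cohort$leaf_id
         else sprintf("leaf_%03d", seq_len(nrow(cohort)))
  gts <- if ("genotype" %in% names(cohort)) cohort$genotype
         else rep(NA_character_, nrow(cohort))
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    c_ <- cohort$contour[[i]]
    lm_ <- find_base_and_apex(c_, n_points = n_points)
    teeth <- detect_teeth(c_, landmarks = lm_, ...)
    bl <- blade_length(c_, lm_$base, lm_$apex)
    di <- leaf_di(c_, alpha = alpha, n_points = n_points,
                  genotype = gts[i], leaf_id = ids[i], blade_length = bl)
    di$tooth_count <- nrow(teeth)
    di$first_tooth_height <- if (nrow(teeth) > 0) {
      min_rank <- teeth[teeth$rank_from_base == 1, ]
      mean(min_rank$height)
    } else NA_real_
    di
  })
  dplyr::bind_rows(rows)
}
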
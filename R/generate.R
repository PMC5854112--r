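#' Parameters for the synthetic leaf generator
#'
#' Bundles and validates the parameters of [generate_leaf()].  The generator
#' emulates young rosette-leaf silhouettes: an ovate blade that tapers
#' gradually into a narrow petiole, with `n_teeth` marginal teeth per side
#' modelled as raised-cosine bumps displaced along the outward normal of the
#' smooth margin.  All geometry is in micrometres.
#'
#' Default proportions (blade width 0.42 of blade length, petiole 0.28 long
#' and 0.09 wide relative to blade length, ovate width profile widest at
#' about 40% of the blade) were chosen once as a realistic stand-in for young
#' Arabidopsis leaf primordia; the gradual, decurrent base keeps the margin
#' concavity mild, which also keeps the alpha-complex of a smooth blade
#' well conditioned.
#'
#' @param blade_length Base-to-apex lamina extent, micrometres.
#' @param blade_width Maximal blade width, micrometres.
#' @param petiole_length,petiole_width Petiole dimensions, micrometres.
#' @param n_teeth Number of teeth per margin side (0 or more).
#' @param tooth_height_frac Tooth height as a fraction of the local blade
#'   half-width, in `[0, 1)`.
#' @param tooth_width_frac Tooth support width as a fraction of the
#'   inter-tooth spacing, in `(0, 1]`.
#' @param noise_amp Amplitude (micrometres) of the smooth band-limited
#'   boundary perturbation; 0 disables noise.
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   leaf bit-for-bit.
#' @return A `leaf_params` list.
#' @examples
#' p <- leaf_params(blade_length = 1000, n_teeth = 4, seed = 1)
#' leaf <- generate_leaf(p)
#' polygon_area(leaf$contour)
#' @export
leaf_params <- function(blade_length = 1000,
                        blade_width = 0.42 * blade_length,
                        petiole_length = 0.28 * blade_length,
                        petiole_width = 0.09 * blade_length,
                        n_teeth = 4,
                        tooth_height_frac = 0.22,
                        tooth_width_frac = 0.5,
                        noise_amp = 0,
                        seed = 1L) {
  p <- list(blade_length = blade_length, blade_width = blade_width,
            petiole_length = petiole_length, petiole_width = petiole_width,
            n_teeth = as.integer(n_teeth),
            tooth_height_frac = tooth_height_frac,
            tooth_width_frac = tooth_width_frac,
            noise_amp = noise_amp, seed = as.integer(seed))
  for (f in c("blade_length", "blade_width", "petiole_length",
              "petiole_width")) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) {
      abort(sprintf("`%s` must be a positive length.", f))
    }
  }
  if (p$n_teeth < 0) abort("`n_teeth` must be >= 0.")
  if (p$tooth_height_frac < 0 || p$tooth_height_frac >= 1) {
    abort("`tooth_height_frac` must be in [0, 1).")
  }
  if (p$tooth_width_frac <= 0 || p$tooth_width_frac > 1) {
    abort("`tooth_width_frac` must be in (0, 1].")
  }
  if (p$noise_amp < 0) abort("`noise_amp` must be >= 0.")
  if (p$petiole_width >= p$blade_width) {
    abort("`petiole_width` must be smaller than `blade_width`.")
  }
  class(p) <- "leaf_params"
  p
}

# ovate half-width profile on u in [0,1]; phi0 = value at the base junction.
# Widest at u = a/(a+b); tapers smoothly (decurrently) into the petiole.
ovate_profile <- function(u, phi0, a = 2.2, b = 3.0) {
  umax <- a / (a + b)
  beta <- (u^a * (1 - u)^b) / (umax^a * (1 - umax)^b)
  phi0 * (1 - u) + (1 - phi0) * beta
}

# fraction of the nominal lamina axis below the neck (profile minimum near
# the base); scale-invariant, depends only on phi0
neck_u <- function(phi0) {
  u <- seq(0, 0.25, length.out = 2001)
  u[which.min(ovate_profile(u, phi0))]
}

#' Generate a synthetic leaf silhouette with ground truth
#'
#' Builds a simple (non-self-intersecting) closed contour for the leaf
#' described by `params`, together with exact ground truth for every quantity
#' the measurement pipeline later estimates: polygon area and perimeter,
#' tooth apex and sinus positions, tooth heights, base and apex landmarks and
#' blade length.
#'
#' Teeth are raised-cosine bumps along the arclength of the smooth lamina
#' margin, displaced along the outward normal; the true apex of a tooth is
#' the displaced bump centre, its true flanking sinuses are the bump's
#' support edges on the un-displaced outline (where the displacement
#' vanishes and the margin curvature has its minima), and the true tooth
#' height is the perpendicular distance from the apex to the chord joining
#' its two flanking sinuses — the same definition the landmark module
#' measures, so recovery tests are like-for-like.  Boundary
#' noise, when requested, is a smooth band-limited normal displacement of the
#' whole outline (Fourier modes 3-15), never per-vertex jitter, and all truth
#' landmarks are displaced with their vertices so the truth stays
#' self-consistent.
#'
#' @param params A [leaf_params()] object.
#' @param n_margin Number of samples along one lamina margin side.
#' @return A list of class `leaf_sim` with elements `contour` (a
#'   [as_leaf_contour()] polygon) and `truth` (list with `polygon`,
#'   `true_area`, `true_perimeter`, `tooth_apices`, `sinus_points`,
#'   `true_tooth_heights`, `tooth_support`, `base_point`, `apex_point`,
#'   `true_blade_length`).
#' @export
generate_leaf <- function(params, n_margin = 400) {
  stopifnot(inherits(params, "leaf_params"))
  p <- params
  phi0 <- (p$petiole_width / 2) / (p$blade_width / 2)
  if (phi0 >= 1) abort("`petiole_width` must be smaller than `blade_width`.")
  un <- neck_u(phi0)
  # nominal axis length so that the true base (neck) to apex distance equals
  # blade_length exactly
  L <- p$blade_length / (1 - un)
  W2 <- p$blade_width / 2
  pw <- p$petiole_width / 2
  pl <- p$petiole_length

  # --- smooth right margin, base junction (u=0) to apex (u=1)
  u <- seq(0, 1, length.out = n_margin)
  xr <- W2 * ovate_profile(u, phi0)
  yr <- L * u
  seg <- sqrt(diff(xr)^2 + diff(yr)^2)
  s <- c(0, cumsum(seg))
  S <- s[length(s)]

  # --- tooth placement along the smooth margin arclength
  margin_lo <- 0.25 * S
  margin_hi <- 0.80 * S
  n_teeth <- p$n_teeth
  teeth <- NULL
  if (n_teeth > 0 && p$tooth_height_frac > 0) {
    slot <- (margin_hi - margin_lo) / n_teeth
    centers <- margin_lo + slot * (seq_len(n_teeth) - 0.5)
    half_support <- p$tooth_width_frac * slot / 2
    if (half_support <= 0) abort("tooth support collapsed; increase tooth_width_frac.")
    teeth <- list(centers = centers, half_support = half_support, slot = slot)
  }

  # refine the arclength sampling so that bump centres, support edges and
  # sinus midpoints fall exactly on vertices
  s_grid <- seq(0, S, length.out = n_margin)
  sneck <- s_neck(s, xr, un, L)
  sin_s <- numeric(0)
  if (!is.null(teeth)) {
    # sinus s-values: the support edges flanking each tooth (where the
    # normal displacement vanishes and the curvature minima sit)
    sin_prox_s <- teeth$centers - teeth$half_support
    sin_dist_s <- teeth$centers + teeth$half_support
    sin_s <- as.vector(rbind(sin_prox_s, sin_dist_s))
    extra <- unlist(lapply(seq_len(n_teeth), function(i) {
      seq(teeth$centers[i] - teeth$half_support,
          teeth$centers[i] + teeth$half_support, length.out = 41)
    }))
    exact <- sort(unique(c(extra, sin_s, teeth$centers, sneck)))
    # collapse floating-point twins (e.g. a seq() endpoint vs the same
    # support edge computed directly): they interpolate to coincident
    # vertices that degenerate the polygon
    exact <- exact[c(TRUE, diff(exact) > 1e-9 * S)]
  } else {
    exact <- sneck
  }
  # drop grid points crowding an exact mark: near-duplicate vertices make
  # the normal-displacement noise fold the outline locally
  tol <- S / (4 * n_margin)
  near <- vapply(s_grid, function(g) any(abs(exact - g) < tol), logical(1))
  s_marks <- sort(unique(c(s_grid[!near], exact)))
  s_marks <- s_marks[s_marks >= 0 & s_marks <= S]

  mx <- stats::approx(s, xr, xout = s_marks, ties = "ordered")$y
  my <- stats::approx(s, yr, xout = s_marks, ties = "ordered")$y

  # outward normal of the right margin (rightward of the upward tangent)
  nm <- length(s_marks)
  ipn <- pmin(nm, seq_len(nm) + 1)
  imn <- pmax(1, seq_len(nm) - 1)
  tx <- mx[ipn] - mx[imn]
  ty <- my[ipn] - my[imn]
  tl <- sqrt(tx^2 + ty^2)
  nx <- ty / tl
  ny <- -tx / tl
  flip <- sign(sum(nx))  # outward = +x on the right margin
  nx <- nx * flip; ny <- ny * flip

  disp <- numeric(nm)
  apex_s <- numeric(0)
  heights <- numeric(0)
  if (!is.null(teeth)) {
    hw_at <- stats::approx(s, xr, xout = teeth$centers, ties = "ordered")$y
    heights <- p$tooth_height_frac * hw_at
    for (i in seq_len(n_teeth)) {
      m <- abs(s_marks - teeth$centers[i]) <= teeth$half_support
      disp[m] <- disp[m] + heights[i] * 0.5 *
        (1 + cos(pi * (s_marks[m] - teeth$centers[i]) / teeth$half_support))
    }
    apex_s <- teeth$centers
  }
  rx <- mx + disp * nx
  ry <- my + disp * ny

  # indices of landmark vertices on the right margin
  apex_idx_r <- if (length(apex_s)) match_closest(apex_s, s_marks) else integer(0)
  sin_idx_r <- if (length(sin_s)) match_closest(sin_s, s_marks) else integer(0)

  # --- assemble full polygon, counter-clockwise:
  # petiole tip cap -> right petiole side -> right margin (base->apex) ->
  # left margin (apex->base, mirrored) -> left petiole side
  cap_t <- seq(0, -pi, length.out = 33)
  cap <- cbind(pw * cos(cap_t), -pl + pw * sin(cap_t))  # right to left below
  pet_r <- cbind(rep(pw, 16), seq(-pl, 0, length.out = 17)[-17])
  pet_l <- cbind(rep(-pw, 16), seq(0, -pl, length.out = 17)[-17])

  right_xy <- cbind(rx, ry)
  left_xy <- cbind(-rev(rx), rev(ry))

  parts <- list(cap[rev(seq_len(nrow(cap))), , drop = FALSE][-1, , drop = FALSE],
                pet_r[-1, , drop = FALSE],
                right_xy,
                left_xy[-1, , drop = FALSE],
                pet_l[-1, , drop = FALSE])
  poly <- do.call(rbind, parts)
  # offsets of the margin blocks inside the polygon
  off_right <- nrow(parts[[1]]) + nrow(parts[[2]])
  off_left <- off_right + nrow(parts[[3]])
  idx_right <- off_right + seq_len(nrow(right_xy))
  idx_left <- off_left + seq_len(nrow(left_xy) - 1)  # first left vertex dropped? no:
  # left_xy had its first row (the apex duplicate) removed
  n_poly <- nrow(poly)

  apex_vertex <- off_right + nm                       # apex (u = 1)
  apex_idx_right <- off_right + apex_idx_r
  sin_idx_right <- off_right + sin_idx_r
  # left margin vertex k corresponds to right margin vertex (nm - k); the
  # apex row was dropped, so right-margin index i maps to off_left + (nm - i)
  apex_idx_left <- off_left + (nm - apex_idx_r)
  sin_idx_left <- off_left + (nm - sin_idx_r)

  # --- smooth band-limited boundary noise (normal displacement)
  if (p$noise_amp > 0) {
    poly <- add_boundary_noise(poly, p$noise_amp, p$seed)
  }

  v <- data.frame(x = poly[, 1], y = poly[, 2])
  if (shoelace_area(v$x, v$y) < 0) {
    # reversal would scramble the landmark indices; orientation is CCW by
    # construction, so this indicates a construction bug
    abort("internal error: generated polygon is not counter-clockwise.")
  }
  dup <- duplicated(round(cbind(v$x, v$y), 9))
  if (any(dup)) {
    keep <- !dup
    remap <- cumsum(keep)
    v <- v[keep, , drop = FALSE]
    apex_vertex <- remap[apex_vertex]
    apex_idx_right <- remap[apex_idx_right]
    apex_idx_left <- remap[apex_idx_left]
    sin_idx_right <- remap[sin_idx_right]
    sin_idx_left <- remap[sin_idx_left]
  }

  contour <- as_leaf_contour(v)
  if (!contour_is_simple(contour)) {
    abort(paste0(
      "generated outline self-intersects; tooth_height_frac = ",
      signif(p$tooth_height_frac, 3), " is too large for tooth_width_frac = ",
      signif(p$tooth_width_frac, 3),
      " (or noise_amp is too large). Reduce tooth height or widen teeth."))
  }

  # --- ground truth (recomputed from the final polygon so it stays
  # self-consistent under boundary noise)
  neck_vertex_r <- off_right + which.min(abs(s_marks - sneck))
  base_r <- as.numeric(contour[neck_vertex_r, c("x", "y")])
  neck_vertex_l <- off_left + (nm - (neck_vertex_r - off_right))
  base_l <- as.numeric(contour[neck_vertex_l, c("x", "y")])
  base_point <- (base_r + base_l) / 2
  apex_point <- as.numeric(contour[apex_vertex, c("x", "y")])

  apices <- sinus <- NULL
  true_heights <- numeric(0)
  tooth_support <- if (!is.null(teeth)) 2 * teeth$half_support else NA_real_
  if (n_teeth > 0 && p$tooth_height_frac > 0) {
    ap_idx <- c(apex_idx_right, apex_idx_left)
    apices <- tibble(
      x = contour$x[ap_idx], y = contour$y[ap_idx],
      side = rep(c("right", "left"), each = n_teeth),
      rank_from_base = rep(seq_len(n_teeth), 2),
      vertex = ap_idx
    )
    si_idx <- c(sin_idx_right, sin_idx_left)
    sinus <- tibble(
      x = contour$x[si_idx], y = contour$y[si_idx],
      side = rep(c("right", "left"), each = 2 * n_teeth),
      rank_from_base = rep(rep(seq_len(n_teeth), each = 2), 2),
      flank = rep(c("prox", "dist"), times = 2 * n_teeth),
      vertex = si_idx
    )
    true_heights <- vapply(seq_len(2 * n_teeth), function(k) {
      side_k <- apices$side[k]
      rk <- apices$rank_from_base[k]
      sp <- sinus[sinus$side == side_k & sinus$rank_from_base == rk &
                    sinus$flank == "prox", ]
      sd_ <- sinus[sinus$side == side_k & sinus$rank_from_base == rk &
                    sinus$flank == "dist", ]
      point_line_distance(c(apices$x[k], apices$y[k]),
                          c(sp$x, sp$y), c(sd_$x, sd_$y))
    }, numeric(1))
  }

  truth <- list(
    polygon = contour,
    true_area = polygon_area(contour),
    true_perimeter = polygon_perimeter(contour),
    tooth_apices = apices,
    sinus_points = sinus,
    true_tooth_heights = true_heights,
    tooth_support = tooth_support,
    base_point = base_point,
    apex_point = apex_point,
    true_blade_length = sqrt(sum((apex_point - base_point)^2))
  )
  structure(list(contour = contour, truth = truth, params = p),
            class = "leaf_sim")
}

# arclength position of the neck (profile minimum) on the smooth margin
s_neck <- function(s, xr, un, L) {
  y_neck <- L * un
  n <- length(s)
  y <- seq(0, L, length.out = n)
  stats::approx(y, s, xout = y_neck, ties = "ordered")$y
}

match_closest <- function(vals, grid) {
  vapply(vals, function(v) which.min(abs(grid - v)), integer(1))
}

# perpendicular distance from point p to the infinite line through a and b
point_line_distance <- function(p, a, b) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) abort("coincident line points; cannot define a chord.")
  abs((b[1] - a[1]) * (a[2] - p[2]) - (a[1] - p[1]) * (b[2] - a[2])) / len
}

# smooth periodic normal displacement, Fourier modes 3..15, max|d| = amp.
# The amplitude is attenuated where the local half-width (distance to the
# construction axis) approaches the noise scale, so the two margins can
# never be pushed across each other near the apex or the petiole tip.
add_boundary_noise <- function(poly, amp, seed) {
  n <- nrow(poly)
  withr::with_seed(seed, {
    modes <- 3:15
    a <- stats::rnorm(length(modes))
    b <- stats::rnorm(length(modes))
    seg <- sqrt(diff(c(poly[, 1], poly[1, 1]))^2 +
                diff(c(poly[, 2], poly[1, 2]))^2)
    s <- c(0, cumsum(seg))[seq_len(n)]
    t <- 2 * pi * s / sum(seg)          # arclength phase
    d <- rowSums(vapply(seq_along(modes), function(k) {
      a[k] * cos(modes[k] * t) + b[k] * sin(modes[k] * t)
    }, numeric(n)))
    d <- d / max(abs(d)) * amp
    tt <- abs(poly[, 1]) / (3 * amp)
    d <- d * tt / sqrt(1 + tt^2)
    # normals from a wide symmetric stencil: stable where vertex spacing
    # is irregular
    ip <- ((seq_len(n) + 1L) %% n) + 1L   # i + 2
    im <- ((seq_len(n) - 5L) %% n) + 1L   # i - 2
    tx <- poly[ip, 1] - poly[im, 1]
    ty <- poly[ip, 2] - poly[im, 2]
    tl <- sqrt(tx^2 + ty^2)
    # outward normal of a CCW polygon is (ty, -tx)/|t|
    poly + cbind(d * ty / tl, -d * tx / tl)
  })
}

#' @export
print.leaf_sim <- function(x, ...) {
  cat(sprintf(
    "<leaf_sim: blade %.0f um, %d teeth/side, %d vertices>\n",
    x$params$blade_length, x$params$n_teeth, nrow(x$contour)))
  invisible(x)
}

#' Generate a cohort of leaves spanning a developmental series
#'
#' Draws `n_leaves` blade lengths uniformly over `blade_range` and generates
#' one leaf per draw from `base` parameters, scaling all linear dimensions
#' with blade length (isometric growth) and multiplying `tooth_height_frac`
#' by `genotype_tooth_scale`.  A scale below 1 emulates a genotype with
#' shallower serration at every stage; blade length serves as the
#' developmental-stage proxy throughout the package.
#'
#' @param base A [leaf_params()] object giving the shape at any size.
#' @param n_leaves Number of leaves (>= 1).
#' @param blade_range Length-2 increasing range of blade lengths, micrometres.
#' @param genotype_tooth_scale Multiplier on `tooth_height_frac`.
#' @param genotype Genotype label recorded in the metadata.
#' @param seed Integer seed for the cohort.
#' @return A tibble with one row per leaf: `leaf_id`, `genotype`,
#'   `blade_length` (true value), and list-columns `contour` and `truth`.
#' @export
generate_cohort <- function(base, n_leaves, blade_range = c(200, 5000),
                            genotype_tooth_scale = 1,
                            genotype = "synthetic", seed = 1L) {
  stopifnot(inherits(base, "leaf_params"))
  if (!is.numeric(n_leaves) || n_leaves < 1) abort("`n_leaves` must be >= 1.")
  if (length(blade_range) != 2 || diff(blade_range) <= 0) {
    abort("`blade_range` must be an increasing length-2 range.")
  }
  n_leaves <- as.integer(n_leaves)
  lengths <- withr::with_seed(seed, stats::runif(n_leaves, blade_range[1],
                                                 blade_range[2]))
  scale0 <- base$blade_length
  rows <- purrr::map(seq_len(n_leaves), function(i) {
    f <- lengths[i] / scale0
    p <- leaf_params(
      blade_length = lengths[i],
      blade_width = base$blade_width * f,
      petiole_length = base$petiole_length * f,
      petiole_width = base$petiole_width * f,
      n_teeth = base$n_teeth,
      tooth_height_frac = base$tooth_height_frac * genotype_tooth_scale,
      tooth_width_frac = base$tooth_width_frac,
      noise_amp = base$noise_amp * f,
      seed = base$seed + i
    )
    sim <- generate_leaf(p)
    tibble(leaf_id = sprintf("%s_%03d", genotype, i),
           genotype = genotype,
           blade_length = sim$truth$true_blade_length,
           contour = list(sim$contour),
           truth = list(sim$truth))
  })
  dplyr::bind_rows(rows)
}

#' Write a generated leaf to disk
#'
#' Writes the contour in the package CSV dialect and the ground truth as a
#' JSON sidecar (`<stem>.json`).
#'
#' @param sim A `leaf_sim` from [generate_leaf()].
#' @param stem Output path without extension.
#' @return The contour path, invisibly.
#' @export
write_leaf <- function(sim, stem) {
  stopifnot(inherits(sim, "leaf_sim"))
  write_contour_csv(sim$contour, paste0(stem, ".csv"))
  tr <- sim$truth
  tr$polygon <- NULL
  tr$tooth_apices <- if (!is.null(tr$tooth_apices)) as.data.frame(tr$tooth_apices)
  tr$sinus_points <- if (!is.null(tr$sinus_points)) as.data.frame(tr$sinus_points)
  jsonlite::write_json(tr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(stem, ".csv"))
}
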
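#' Locate the base and apex landmarks of a leaf contour
#'
#' The base is the petiole/lamina junction: the contour is oriented by its
#' principal axis, a petiole is declared when one end of the silhouette
#' shows an extended terminal run of sections narrower than 25% of the
#' maximal width, and the junction is located as the neck — the narrowest
#' section between petiole and blade — collapsed to the midpoint of the two
#' margin points flanking it.
#' Without a petiole the base is the extreme vertex at the low end of the
#' principal axis.  The apex is the margin vertex farthest from the base
#' along the principal axis.
#'
#' @param c A contour.
#' @param n_points Uniform resampling used internally.
#' @return A list of class `leaf_landmarks`: `base` and `apex` (one-row
#'   tibbles with `kind`, `x`, `y`, `contour_index`), `contour` (the
#'   resampled contour the indices refer to), `has_petiole`, `neck_left`
#'   and `neck_right` (margin vertex indices bounding the lamina), and
#'   `axis` (unit principal-axis vector pointing base to apex).
#' @export
find_base_and_apex <- function(c, n_points = 2048) {
  check_contour(c)
  # canonical start vertex: makes the resampling grid (and hence every
  # downstream landmark) equivariant under x-mirroring
  k0 <- which.min(c$y)
  if (k0 > 1) {
    idx <- c(k0:nrow(c), 1:(k0 - 1))
    c <- new_leaf_contour(c[idx, , drop = FALSE],
                          pixel_size = attr(c, "pixel_size"))
  }
  rc <- resample_contour(c, n_points)
  n <- nrow(rc)
  V <- cbind(rc$x, rc$y)
  ctr <- colMeans(V)
  Q <- sweep(V, 2, ctr)
  # closed-form principal axes of the 2x2 vertex covariance
  sxx <- sum(Q[, 1]^2) / n
  syy <- sum(Q[, 2]^2) / n
  sxy <- sum(Q[, 1] * Q[, 2]) / n
  disc <- sqrt((sxx - syy)^2 + 4 * sxy^2)
  lam1 <- (sxx + syy + disc) / 2
  lam2 <- (sxx + syy - disc) / 2
  if (lam2 / lam1 > 0.9) {
    abort("cannot orient contour: principal axes are degenerate (near-circular shape).")
  }
  theta <- 0.5 * atan2(2 * sxy, sxx - syy)
  v1 <- c(cos(theta), sin(theta))
  v2 <- c(-v1[2], v1[1])
  t_ <- as.numeric(Q %*% v1)
  w_ <- as.numeric(Q %*% v2)

  nb <- 48L
  brk <- seq(min(t_), max(t_), length.out = nb + 1)
  bin <- pmin(pmax(findInterval(t_, brk, all.inside = TRUE), 1L), nb)
  width <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    wk <- w_[bin == k]
    if (length(wk) >= 3) width[k] <- max(wk) - min(wk)
  }
  ok <- which(!is.na(width))
  max_width <- max(width, na.rm = TRUE)
  wmax_bin <- ok[which.max(width[ok])]

  # a petiole is an extended terminal run of narrow sections; a tapering
  # blade tip is narrow too, but only over a couple of bins
  narrow <- width[ok] < 0.25 * max_width
  run_lo <- if (narrow[1]) which.min(c(narrow, FALSE)) - 1L else 0L
  rev_narrow <- rev(narrow)
  run_hi <- if (rev_narrow[1]) which.min(c(rev_narrow, FALSE)) - 1L else 0L
  has_petiole <- max(run_lo, run_hi) >= 3L && run_lo != run_hi
  if (has_petiole && run_hi > run_lo) {
    # flip the axis so the petiole sits at the low end
    v1 <- -v1; v2 <- c(-v1[2], v1[1])
    t_ <- -t_
    w_ <- as.numeric(Q %*% v2)
    brk <- seq(min(t_), max(t_), length.out = nb + 1)
    bin <- pmin(pmax(findInterval(t_, brk, all.inside = TRUE), 1L), nb)
    width <- rep(NA_real_, nb)
    for (k in seq_len(nb)) {
      wk <- w_[bin == k]
      if (length(wk) >= 3) width[k] <- max(wk) - min(wk)
    }
    ok <- which(!is.na(width))
    wmax_bin <- ok[which.max(width[ok])]
  }

  apex_idx <- which.max(t_)

  if (has_petiole) {
    # Localize the neck by fitting the half-width profile with a
    # constant-petiole + quadratic-flare hinge model |w| = a + b*(t-tau)+^2
    # over the junction region; the hinge position tau is the neck.  The
    # fit averages over hundreds of margin vertices, which keeps the base
    # stable when smooth boundary noise is comparable to the neck depth.
    flare_top <- ok[which(width[ok] >= 0.5 * max_width)[1]]
    lo_t <- brk[min(ok[1] + 1L, nb)]       # skip the rounded petiole tip
    hi_t <- brk[flare_top]
    reg <- which(t_ >= lo_t & t_ <= hi_t)
    rr_ <- abs(w_[reg]); tt_ <- t_[reg]
    taus <- seq(lo_t, hi_t, length.out = 80)
    sse <- vapply(taus, function(tau) {
      h <- pmax(0, tt_ - tau)^2
      fit <- stats::lm.fit(cbind(1, h), rr_)
      sum(fit$residuals^2)
    }, numeric(1))
    tau <- taus[which.min(sse)]
    candL <- which(w_ > 0 & t_ >= lo_t & t_ <= hi_t)
    candR <- which(w_ < 0 & t_ >= lo_t & t_ <= hi_t)
    iL <- candL[which.min(abs(t_[candL] - tau))]
    iR <- candR[which.min(abs(t_[candR] - tau))]
    base_xy <- (V[iL, ] + V[iR, ]) / 2
    base_idx <- which.min((rc$x - base_xy[1])^2 + (rc$y - base_xy[2])^2)
    neck_left <- iL
    neck_right <- iR
  } else {
    base_idx <- which.min(t_)
    base_xy <- V[base_idx, ]
    neck_left <- neck_right <- base_idx
  }

  axis_vec <- c(rc$x[apex_idx], rc$y[apex_idx]) - base_xy
  axis_vec <- axis_vec / sqrt(sum(axis_vec^2))

  out <- list(
    base = tibble(kind = "base", x = base_xy[1], y = base_xy[2],
                  contour_index = base_idx),
    apex = tibble(kind = "apex", x = rc$x[apex_idx], y = rc$y[apex_idx],
                  contour_index = apex_idx),
    contour = rc,
    has_petiole = has_petiole,
    neck_left = neck_left,
    neck_right = neck_right,
    axis = axis_vec
  )
  class(out) <- "leaf_landmarks"
  out
}

#' @export
print.leaf_landmarks <- function(x, ...) {
  cat(sprintf("<leaf_landmarks: base (%.1f, %.1f), apex (%.1f, %.1f), petiole %s>\n",
              x$base$x, x$base$y, x$apex$x, x$apex$y,
              if (x$has_petiole) "detected" else "absent"))
  invisible(x)
}

#' Blade length of a leaf
#'
#' Euclidean distance between the base and apex landmarks (petiole
#' excluded); the package-wide proxy for developmental stage.
#'
#' @param c A contour (used only when `base`/`apex` are missing).
#' @param base,apex Landmark rows from [find_base_and_apex()]; computed from
#'   `c` when omitted.
#' @return Blade length in micrometres.
#' @export
blade_length <- function(c, base = NULL, apex = NULL) {
  if (is.null(base) || is.null(apex)) {
    lm_ <- find_base_and_apex(c)
    base <- lm_$base; apex <- lm_$apex
  }
  sqrt((apex$x - base$x)^2 + (apex$y - base$y)^2)
}

cyclic_seq <- function(i, j, n) {
  if (i <= j) i:j else c(i:n, 1:j)
}

#' Detect marginal teeth from contour curvature
#'
#' Tooth apices are local maxima of the signed curvature on the lamina margin
#' between base and apex on each side (the leaf apex itself and the petiole
#' margin are excluded); the flanking sinuses of each apex are the nearest
#' curvature local minima on either side.  Candidates with curvature
#' prominence below `min_prominence` or apex-to-sinus-chord height below
#' `min_height` are discarded; surviving teeth are ranked from the base on
#' each side.
#'
#' @param c A contour.
#' @param profile Optional [curvature_profile()] of the landmark-resampled
#'   contour; computed when omitted.
#' @param min_prominence Curvature prominence threshold (1/micrometres);
#'   default 5 times the median absolute curvature of the contour.
#' @param min_height Minimal tooth height (micrometres); default 1% of the
#'   blade length.
#' @param landmarks Optional result of [find_base_and_apex()]; computed when
#'   omitted.
#' @param n_points Resampling used when `landmarks` is computed here.
#' @return A `leaf_teeth` tibble, one row per tooth: `side`,
#'   `rank_from_base`, apex coordinates and index, both sinus coordinates and
#'   indices, `height` (micrometres) and `prominence` (1/micrometres).  An
#'   empty tibble is a valid result.
#' @export
detect_teeth <- function(c, profile = NULL, min_prominence = NULL,
                         min_height = NULL, landmarks = NULL,
                         n_points = 2048) {
  if (is.null(landmarks)) landmarks <- find_base_and_apex(c, n_points = n_points)
  rc <- landmarks$contour
  n <- nrow(rc)
  # finer smoothing than the general-purpose default: landmark positions
  # shift with the smoothing scale, and tooth supports are narrow
  if (is.null(profile)) {
    profile <- curvature_profile(rc, sigma = polygon_perimeter(rc) / 400)
  }
  kap <- profile$kappa
  # minimally smoothed profile for landmark refinement: the detection-scale
  # smoothing biases extremum positions inward by about its sigma
  kfine <- curvature_profile(rc, sigma = 3 * polygon_perimeter(rc) / n)$kappa
  bl <- blade_length(rc, landmarks$base, landmarks$apex)
  if (is.null(min_prominence)) min_prominence <- 5 * median(abs(kap))
  if (is.null(min_height)) min_height <- 0.01 * bl
  apex_idx <- landmarks$apex$contour_index

  side_indices <- function(neck_idx) {
    fwd <- cyclic_seq(neck_idx, apex_idx, n)
    other <- setdiff(c(landmarks$neck_left, landmarks$neck_right), neck_idx)
    if (length(other) == 1 && other %in% fwd[-c(1, length(fwd))]) {
      fwd <- rev(cyclic_seq(apex_idx, neck_idx, n))
    }
    fwd  # ordered base -> apex
  }

  collect_side <- function(neck_idx) {
    idx <- side_indices(neck_idx)
    m <- length(idx)
    if (m < 7) return(NULL)
    # exclude the apex neighbourhood and the neck itself
    apex_excl <- ceiling(0.02 * n)
    neck_excl <- ceiling(0.01 * n)
    usable <- seq_len(m) > neck_excl & seq_len(m) <= m - apex_excl
    kv <- kap[idx]
    interior <- 2:(m - 1)
    is_max <- c(FALSE, kv[interior] > kv[interior - 1] &
                        kv[interior] >= kv[interior + 1], FALSE)
    cand <- which(is_max & usable)
    if (length(cand) == 0) return(NULL)
    rows <- lapply(cand, function(p) {
      # nearest local minima on both sides of the peak
      lmin <- p
      while (lmin > 1 &&
             !(kv[lmin] < kv[min(lmin + 1, m)] && kv[lmin] <= kv[max(lmin - 1, 1)]))
        lmin <- lmin - 1
      rmin <- p
      while (rmin < m &&
             !(kv[rmin] < kv[max(rmin - 1, 1)] && kv[rmin] <= kv[min(rmin + 1, m)]))
        rmin <- rmin + 1
      prom <- kv[p] - max(kv[lmin], kv[rmin])
      # refine extremum positions on the minimally smoothed profile
      wr <- max(2L, ceiling(n / 200))
      refine <- function(i0, maximum) {
        win <- max(1, i0 - wr):min(m, i0 + wr)
        kw <- kfine[idx[win]]
        win[if (maximum) which.max(kw) else which.min(kw)]
      }
      p_f <- refine(p, TRUE)
      lmin_f <- refine(lmin, FALSE)
      rmin_f <- refine(rmin, FALSE)
      ap <- c(rc$x[idx[p_f]], rc$y[idx[p_f]])
      sp <- c(rc$x[idx[lmin_f]], rc$y[idx[lmin_f]])
      sd_ <- c(rc$x[idx[rmin_f]], rc$y[idx[rmin_f]])
      if (all(sp == sd_)) return(NULL)
      h <- point_line_distance(ap, sp, sd_)
      tibble(pos = p, apex_index = idx[p_f], apex_x = ap[1], apex_y = ap[2],
             sinus_prox_index = idx[lmin_f], sinus_prox_x = sp[1], sinus_prox_y = sp[2],
             sinus_dist_index = idx[rmin_f], sinus_dist_x = sd_[1], sinus_dist_y = sd_[2],
             height = h, prominence = prom)
    })
    out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
    if (nrow(out) == 0) return(NULL)
    out <- out[out$prominence >= min_prominence & out$height >= min_height, ,
               drop = FALSE]
    if (nrow(out) == 0) return(NULL)
    out <- out[order(out$pos), , drop = FALSE]
    out$rank_from_base <- seq_len(nrow(out))
    out$pos <- NULL
    out
  }

  bx <- landmarks$base$x; by <- landmarks$base$y
  ax_ <- landmarks$axis
  res <- list()
  for (neck_idx in unique(c(landmarks$neck_right, landmarks$neck_left))) {
    side_rows <- collect_side(neck_idx)
    if (!is.null(side_rows)) {
      crossp <- ax_[1] * (side_rows$apex_y - by) - ax_[2] * (side_rows$apex_x - bx)
      side_rows$side <- ifelse(crossp > 0, "left", "right")
      res[[length(res) + 1]] <- side_rows
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble(apex_index = integer(0), apex_x = numeric(0), apex_y = numeric(0),
           sinus_prox_index = integer(0), sinus_prox_x = numeric(0),
           sinus_prox_y = numeric(0), sinus_dist_index = integer(0),
           sinus_dist_x = numeric(0), sinus_dist_y = numeric(0),
           height = numeric(0), prominence = numeric(0),
           rank_from_base = integer(0), side = character(0))
  out <- out[, c("side", "rank_from_base", "apex_index", "apex_x", "apex_y",
                 "sinus_prox_index", "sinus_prox_x", "sinus_prox_y",
                 "sinus_dist_index", "sinus_dist_x", "sinus_dist_y",
                 "height", "prominence")]
  class(out) <- c("leaf_teeth", class(tibble()))
  attr(out, "landmarks") <- landmarks
  out
}

#' Tooth height from apex and flanking sinuses
#'
#' Recomputes the height of each tooth in a teeth table: the perpendicular
#' distance from the apex to the infinite line through the two flanking
#' sinus points.
#'
#' @param teeth A `leaf_teeth` tibble from [detect_teeth()] (or any tibble
#'   with the same apex/sinus coordinate columns).
#' @return Numeric vector of heights, micrometres.
#' @export
tooth_height <- function(teeth) {
  need <- c("apex_x", "apex_y", "sinus_prox_x", "sinus_prox_y",
            "sinus_dist_x", "sinus_dist_y")
  if (!all(need %in% names(teeth))) {
    abort("`teeth` must contain apex and sinus coordinate columns.")
  }
  if (nrow(teeth) == 0) return(numeric(0))
  vapply(seq_len(nrow(teeth)), function(i) {
    point_line_distance(
      c(teeth$apex_x[i], teeth$apex_y[i]),
      c(teeth$sinus_prox_x[i], teeth$sinus_prox_y[i]),
      c(teeth$sinus_dist_x[i], teeth$sinus_dist_y[i]))
  }, numeric(1))
}
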
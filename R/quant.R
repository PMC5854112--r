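#' Robust local background around a seed point
#'
#' Estimates the background level of a fluorescence image in an annulus
#' centred on the seed point: the level is the median intensity over pixels
#' with distance in `[r_in, r_out]` from the seed, and the spread is the
#' normal-consistent median absolute deviation (`1.4826 * MAD`) of the same
#' pixels.  Centring the background on the zone to be quantified removes
#' user-placement bias; the median/MAD pair keeps the estimate stable when a
#' minority of annulus pixels are contaminated by signal or saturation.
#'
#' @param image Numeric intensity matrix.
#' @param seed `c(row, col)` seed point (pixels, 1-based).
#' @param r_in,r_out Inner and outer annulus radii in pixels
#'   (`r_out > r_in > 0`).
#' @return A list with `background_level` and `spread`.
#' @export
local_background <- function(image, seed, r_in, r_out) {
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  if (!(r_out > r_in && r_in > 0)) abort("need r_out > r_in > 0.")
  nr <- nrow(image); nc <- ncol(image)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rr - seed[1])^2 + (cc - seed[2])^2)
  sel <- d >= r_in & d <= r_out
  if (!any(sel)) abort("background annulus lies fully outside the image.")
  v <- image[sel]
  list(background_level = median(v), spread = mad(v, constant = 1.4826))
}

#' Segment the above-background zone containing a seed
#'
#' Thresholds the image at `background_level + k * spread` and returns the
#' 8-connected component of above-threshold pixels that contains the seed;
#' the mask is empty when the seed itself is below threshold.
#'
#' @inheritParams local_background
#' @param background_level,spread Background estimate, e.g. from
#'   [local_background()].
#' @param k Threshold multiplier (>= 0); default 3.
#' @return A logical matrix of the same shape as `image`.
#' @export
segment_zone <- function(image, seed, background_level, spread, k = 3) {
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  if (k < 0) abort("`k` must be >= 0.")
  thr <- background_level + k * spread
  above <- image > thr
  out <- matrix(FALSE, nrow(image), ncol(image))
  sr <- round(seed[1]); sc <- round(seed[2])
  if (sr < 1 || sr > nrow(image) || sc < 1 || sc > ncol(image)) {
    abort("seed outside the image.")
  }
  if (!above[sr, sc]) return(out)
  lab <- .label_components_cpp(above, 8L)
  out[lab == lab[sr, sc]] <- TRUE
  out
}

#' Accumulated above-background intensity over a zone
#'
#' Sums `pixel - background_level` over the zone mask, clipping negative
#' terms at zero (zone pixels are above threshold by construction; clipping
#' only guards numerical edge cases).
#'
#' @inheritParams segment_zone
#' @param zone_mask Logical matrix from [segment_zone()].
#' @param raw_sum Sum raw intensities instead of background-subtracted ones.
#' @return Accumulated intensity (intensity-pixel units); 0 for an empty
#'   zone.
#' @export
accumulated_intensity <- function(image, zone_mask, background_level,
                                  raw_sum = FALSE) {
  if (!identical(dim(image), dim(zone_mask))) {
    abort("`zone_mask` must match the image dimensions.")
  }
  if (!any(zone_mask)) return(0)
  if (raw_sum) return(sum(image[zone_mask]))
  sum(pmax(image[zone_mask] - background_level, 0))
}

#' Seeded zone quantification
#'
#' One-call wrapper for the semi-automatic zone quantification: estimate the
#' local background around the seed, segment the above-background zone
#' containing it, and accumulate the background-subtracted intensity.  The
#' seed point is the only manual input; everything else is automatic.
#'
#' @inheritParams local_background
#' @param r_in,r_out Annulus radii; defaults are 1.5 and 3 times
#'   `zone_radius`.
#' @param zone_radius Expected zone radius in pixels (sets the annulus
#'   defaults).
#' @param k Threshold multiplier.
#' @param raw_sum Accumulate raw rather than background-subtracted
#'   intensity.
#' @param snap_radius Seed-click tolerance in pixels: the flood seed is
#'   moved to the brightest pixel within this radius, so a click on a noise
#'   dip inside the zone does not yield an empty mask.  0 disables.
#' @return An object of class `zone_quant`: list with `zone_mask`,
#'   `background_level`, `spread`, `accumulated_intensity`, `zone_area`,
#'   `seed`, `params`.  Use [tidy()] for a one-row tibble.
#' @export
quantify_zone <- function(image, seed, zone_radius = 15,
                          r_in = 1.5 * zone_radius, r_out = 3 * zone_radius,
                          k = 3, raw_sum = FALSE, snap_radius = 2) {
  bg <- local_background(image, seed, r_in, r_out)
  if (snap_radius > 0) {
    rr <- row(image); cc <- col(image)
    near <- (rr - seed[1])^2 + (cc - seed[2])^2 <= snap_radius^2
    idx <- which(near)[which.max(image[near])]
    seed <- c((idx - 1) %% nrow(image) + 1, (idx - 1) %/% nrow(image) + 1)
  }
  mask <- segment_zone(image, seed, bg$background_level, bg$spread, k)
  acc <- accumulated_intensity(image, mask, bg$background_level,
                               raw_sum = raw_sum)
  structure(list(
    zone_mask = mask,
    background_level = bg$background_level,
    spread = bg$spread,
    accumulated_intensity = acc,
    zone_area = sum(mask),
    seed = seed,
    params = list(r_in = r_in, r_out = r_out, k = k, raw_sum = raw_sum)
  ), class = "zone_quant")
}

#' @export
print.zone_quant <- function(x, ...) {
  cat(sprintf(
    "<zone_quant: background %.4g (spread %.3g), zone %d px, accumulated %.6g>\n",
    x$background_level, x$spread, x$zone_area, x$accumulated_intensity))
  invisible(x)
}

#' @export
tidy.zone_quant <- function(x, ...) {
  tibble(seed_row = x$seed[1], seed_col = x$seed[2],
         background_level = x$background_level, spread = x$spread,
         zone_area = x$zone_area,
         accumulated_intensity = x$accumulated_intensity,
         k = x$params$k)
}

#' Quantify zones for a batch of seeds
#'
#' Batch mode of [quantify_zone()]: one row of results per seed.
#'
#' @param image Numeric intensity matrix.
#' @param seeds A data frame with columns `seed_row`/`seed_col` (or
#'   `seed_x`/`seed_y`, interpreted as column/row), optionally `label`.
#' @param ... Passed to [quantify_zone()].
#' @return A tibble, one row per seed.
#' @export
quantify_zones <- function(image, seeds, ...) {
  stopifnot(is.data.frame(seeds))
  if (all(c("seed_x", "seed_y") %in% names(seeds))) {
    seeds$seed_col <- seeds$seed_x
    seeds$seed_row <- seeds$seed_y
  }
  rows <- purrr::map(seq_len(nrow(seeds)), function(i) {
    res <- tidy(quantify_zone(image, c(seeds$seed_row[i], seeds$seed_col[i]), ...))
    if ("label" %in% names(seeds)) res$label <- seeds$label[i]
    res
  })
  dplyr::bind_rows(rows)
}

# separable Gaussian blur (truncated at 4 sigma, renormalized at borders)
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(M) {
    n <- nrow(M)
    out <- matrix(0, n, ncol(M))
    for (j in -r:r) {
      src <- pmin(pmax(seq_len(n) + j, 1L), n)  # replicate borders
      out <- out + k[j + r + 1] * M[src, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(image))))
}

#' Detect nucleus-like spots
#'
#' Candidate centroids are local maxima of the band-pass
#' (difference-of-Gaussians at `spot_sigma` and `2 * spot_sigma`) filtered
#' image inside the region of interest, kept in decreasing filter response
#' with a minimal mutual separation; each detection is measured as the mean
#' raw intensity in a disk of radius `2 * spot_sigma` at the centroid.
#'
#' @param image Numeric intensity matrix.
#' @param roi_mask Optional logical matrix restricting the search (e.g. a
#'   sinus region); whole image when `NULL`.
#' @param spot_sigma Expected spot scale in pixels.
#' @param min_separation Minimal distance between detections, pixels.
#' @param threshold Minimal band-pass response; default 3 robust SDs of the
#'   band-pass image above its median.
#' @return A tibble with `row`, `col`, `mean_intensity`, `response`, sorted
#'   by decreasing `mean_intensity`.  Empty when nothing is found.
#' @export
detect_nuclei <- function(image, roi_mask = NULL, spot_sigma = 2,
                          min_separation = 2 * spot_sigma, threshold = NULL) {
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(roi_mask)) abort("`roi_mask` is empty.")
  dog <- gaussian_blur(image, spot_sigma) - gaussian_blur(image, 2 * spot_sigma)
  if (is.null(threshold)) {
    # robust noise scale, with a floor relative to the dynamic range so
    # that numerically flat regions do not spawn spurious maxima
    threshold <- max(median(dog) + 3 * mad(dog, constant = 1.4826),
                     median(dog) + 0.02 * (max(dog) - median(dog)))
  }
  nr <- nrow(image); nc <- ncol(image)
  # strict 8-neighbour local maxima (interior pixels only)
  shift <- function(M, dr, dc) {
    out <- matrix(-Inf, nr, nc)
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    out[r1, c1] <- M[r1 - dr, c1 - dc]
    out
  }
  is_max <- dog > threshold & roi_mask
  for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    is_max <- is_max & dog >= shift(dog, d[1], d[2])
  }
  idx <- which(is_max)
  if (length(idx) == 0) {
    return(tibble(row = integer(0), col = integer(0),
                  mean_intensity = numeric(0), response = numeric(0)))
  }
  pr <- (idx - 1) %% nr + 1
  pc <- (idx - 1) %/% nr + 1
  o <- order(dog[idx], decreasing = TRUE)
  pr <- pr[o]; pc <- pc[o]; resp <- dog[idx][o]
  keep <- logical(length(pr))
  for (i in seq_along(pr)) {
    if (i == 1) { keep[1] <- TRUE; next }
    ki <- which(keep)
    keep[i] <- all((pr[ki] - pr[i])^2 + (pc[ki] - pc[i])^2 >=
                     min_separation^2)
  }
  pr <- pr[keep]; pc <- pc[keep]; resp <- resp[keep]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mi <- vapply(seq_along(pr), function(i) {
    disk <- (rr - pr[i])^2 + (cc - pc[i])^2 <= (2 * spot_sigma)^2
    mean(image[disk])
  }, numeric(1))
  out <- tibble(row = pr, col = pc, mean_intensity = mi, response = resp)
  out[order(-out$mean_intensity), ]
}

#' Mean of the k most intense nuclei
#'
#' Sorts detections by mean intensity and averages the top `min(k, n)`.
#' When fewer than `k` nuclei are available the statistic is still computed
#' but flagged as underpowered.
#'
#' @param nuclei A non-empty tibble from [detect_nuclei()] (or any data
#'   frame with `mean_intensity`).
#' @param k Number of nuclei to average (default 12).
#' @return A one-row tibble: `mean_top_k`, `k`, `n_available`,
#'   `underpowered`.
#' @export
top_k_mean <- function(nuclei, k = 12) {
  if (!is.data.frame(nuclei) || !"mean_intensity" %in% names(nuclei)) {
    abort("`nuclei` must be a data frame with a `mean_intensity` column.")
  }
  n <- nrow(nuclei)
  if (n == 0) abort("no nuclei to summarize.")
  v <- sort(nuclei$mean_intensity, decreasing = TRUE)
  kk <- min(k, n)
  tibble(mean_top_k = mean(v[seq_len(kk)]), k = k, n_available = n,
         underpowered = n < k)
}
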
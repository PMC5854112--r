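#' Generate a synthetic fluorescence image with ground truth
#'
#' Builds a 2-D intensity raster emulating a reporter micrograph: a smooth
#' inhomogeneous background (flat, linear gradient, or broad Gaussian), one
#' compact above-background signal zone (a disk of stated amplitude), a set
#' of Gaussian nucleus spots of stated peak intensities, and optional
#' additive Gaussian noise.  The returned truth records the exact zone mask,
#' the summed zone signal above background, the noiseless background field
#' and the per-nucleus true mean intensity (mean of the noiseless image in a
#' disk of radius `2 * sigma` at the centre — the same statistic the
#' measurement side uses).
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param background A list: `list(type = "flat", level = )`, or
#'   `list(type = "gradient", level = , gx = , gy = )` (intensity per pixel),
#'   or `list(type = "gaussian", level = , amplitude = , center = c(r, c),
#'   sigma = )`.
#' @param zone `NULL`, or a list `list(center = c(r, c), radius = pixels,
#'   amplitude = )`.
#' @param nuclei `NULL`, or a data frame with columns `row`, `col`, `peak`
#'   and optional `sigma` (default `spot_sigma`).
#' @param spot_sigma Default Gaussian sigma of nucleus spots, pixels.
#' @param noise_sd Standard deviation of additive Gaussian noise; 0 disables.
#' @param seed Integer seed (used only for the noise).
#' @return A list of class `fluor_sim`: `image` (numeric matrix) and `truth`
#'   (list with `zone_mask`, `zone_total_signal`, `background_field`,
#'   `nuclei` tibble with `true_mean_intensity`).
#' @export
generate_fluor_image <- function(shape = c(256, 256),
                                 background = list(type = "flat", level = 100),
                                 zone = NULL, nuclei = NULL,
                                 spot_sigma = 2, noise_sd = 0, seed = 1L) {
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (nr < 8 || nc < 8) abort("image too small.")
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  bg <- switch(background$type,
    flat = matrix(background$level, nr, nc),
    gradient = background$level + background$gx * (cc - 1) +
               background$gy * (rr - 1),
    gaussian = background$level + background$amplitude *
      exp(-((rr - background$center[1])^2 + (cc - background$center[2])^2) /
            (2 * background$sigma^2)),
    abort("unknown background type.")
  )

  zone_mask <- matrix(FALSE, nr, nc)
  zone_signal <- matrix(0, nr, nc)
  if (!is.null(zone)) {
    zc <- zone$center
    if (zc[1] - zone$radius < 1 || zc[1] + zone$radius > nr ||
        zc[2] - zone$radius < 1 || zc[2] + zone$radius > nc) {
      abort("zone extends outside the image.")
    }
    d2 <- (rr - zc[1])^2 + (cc - zc[2])^2
    zone_mask <- d2 <= zone$radius^2
    zone_signal[zone_mask] <- zone$amplitude
  }

  spot_field <- matrix(0, nr, nc)
  nuc_truth <- NULL
  if (!is.null(nuclei) && nrow(nuclei) > 0) {
    if (any(nuclei$row < 1 | nuclei$row > nr | nuclei$col < 1 |
            nuclei$col > nc)) {
      abort("nucleus centroid outside the image.")
    }
    sig <- if ("sigma" %in% names(nuclei)) nuclei$sigma else
      rep(spot_sigma, nrow(nuclei))
    for (i in seq_len(nrow(nuclei))) {
      d2 <- (rr - nuclei$row[i])^2 + (cc - nuclei$col[i])^2
      spot_field <- spot_field +
        nuclei$peak[i] * exp(-d2 / (2 * sig[i]^2)) * (d2 <= (4 * sig[i])^2)
    }
    nuc_truth <- tibble(row = nuclei$row, col = nuclei$col,
                        peak = nuclei$peak, sigma = sig)
  }

  clean <- bg + zone_signal + spot_field
  img <- clean
  if (noise_sd > 0) {
    img <- img + withr::with_seed(seed,
      matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc))
  }

  if (!is.null(nuc_truth)) {
    nuc_truth$true_mean_intensity <- vapply(seq_len(nrow(nuc_truth)), function(i) {
      d2 <- (rr - nuc_truth$row[i])^2 + (cc - nuc_truth$col[i])^2
      disk <- d2 <= (2 * nuc_truth$sigma[i])^2
      mean(clean[disk])
    }, numeric(1))
  }

  truth <- list(
    zone_mask = zone_mask,
    zone_total_signal = sum(zone_signal[zone_mask]),
    background_field = bg,
    nuclei = nuc_truth
  )
  structure(list(image = img, truth = truth), class = "fluor_sim")
}

#' Read and write 16-bit fluorescence TIFFs
#'
#' Intensities are stored as 16-bit grayscale; on read they are rescaled to
#' the native 0-65535 range.
#'
#' @param image Numeric matrix with values in `[0, 65535]`.
#' @param path File path.
#' @return `read_fluor_tiff()` returns a numeric matrix;
#'   `write_fluor_tiff()` returns `path` invisibly.
#' @export
write_fluor_tiff <- function(image, path) {
  img <- pmin(pmax(image / 65535, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_fluor_tiff
#' @export
read_fluor_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 65535
}
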
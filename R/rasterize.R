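#' Rasterize a contour to a binary mask
#'
#' Scan-converts the closed polygon into a logical matrix: a pixel is
#' foreground when its centre lies inside the polygon (even-odd rule).  The
#' image is padded by at least 2 pixels of background on every side, so the
#' silhouette never touches the border.
#'
#' Coordinate convention (shared with [extract_contour()]): pixel `(r, c)`
#' (1-based matrix indices, row 1 at the top) has its centre at
#' `x = (c - 1) * pixel_size`, `y = (nrow - r) * pixel_size`, so that
#' counter-clockwise in math coordinates matches the contour orientation
#' invariant.
#'
#' @param c A contour in micrometres.
#' @param pixel_size Pixel size in micrometres (> 0, and no larger than the
#'   contour's bounding box).
#' @param pad Background padding in pixels (minimum 2).
#' @return A logical matrix with attributes `pixel_size` and `origin` (the
#'   micrometre coordinates of the centre of the bottom-left pixel).
#' @export
rasterize_contour <- function(c, pixel_size, pad = 3L) {
  check_contour(c)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number.")
  }
  pad <- max(2L, as.integer(pad))
  bbox_w <- diff(range(c$x))
  bbox_h <- diff(range(c$y))
  if (pixel_size > max(bbox_w, bbox_h)) {
    abort("`pixel_size` is larger than the contour's bounding box.")
  }
  x0 <- min(c$x) - pad * pixel_size
  y0 <- min(c$y) - pad * pixel_size
  nc <- ceiling(bbox_w / pixel_size) + 2L * pad + 1L
  nr <- ceiling(bbox_h / pixel_size) + 2L * pad + 1L
  xs <- x0 + (seq_len(nc) - 1) * pixel_size          # pixel-centre x by col
  ys <- y0 + (seq_len(nr) - 1) * pixel_size          # pixel-centre y, bottom-up
  px <- c$x; py <- c$y
  n <- length(px)
  j <- c(2:n, 1)
  x2 <- px[j]; y2 <- py[j]
  mask <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    yc <- ys[r]
    # edges straddling the scanline (half-open in y to handle vertices)
    str <- (py <= yc & y2 > yc) | (y2 <= yc & py > yc)
    if (!any(str)) next
    xc <- px[str] + (yc - py[str]) * (x2[str] - px[str]) / (y2[str] - py[str])
    xc <- sort(xc)
    inside <- findInterval(xs, xc) %% 2L == 1L
    mask[nr - r + 1L, ] <- inside                    # row 1 = top
  }
  attr(mask, "pixel_size") <- pixel_size
  attr(mask, "origin") <- c(x = x0, y = y0)
  mask
}

#' Read and write binary silhouette masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with foreground white.
#'
#' @param mask A logical matrix (row 1 = top of the image).
#' @param path File path.
#' @return `read_mask_png()` returns a logical matrix; `write_mask_png()`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
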
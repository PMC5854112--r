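test_that("polygon area and perimeter match analytic shapes", {
  sq <- as_leaf_contour(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_perimeter(sq), 4)

  poly <- as_leaf_contour(regular_polygon(4096))
  expect_equal(polygon_area(poly), pi, tolerance = 1e-4)
  expect_equal(polygon_perimeter(poly), 2 * pi, tolerance = 1e-4)
})

test_that("area agrees with an ear-clipping triangulation oracle on random simple polygons", {
  set.seed(11)
  for (rep in 1:5) {
    # star-shaped random polygon: always simple
    n <- 20
    th <- sort(stats::runif(n, 0, 2 * pi))
    r <- stats::runif(n, 0.5, 2)
    df <- data.frame(x = r * cos(th), y = r * sin(th))
    c_ <- as_leaf_contour(df)
    expect_equal(polygon_area(c_), earclip_area(df$x, df$y),
                 tolerance = 1e-9)
  }
})

test_that("contours are normalized to counter-clockwise and reject degenerate input", {
  cw <- data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 1, 0))  # clockwise
  c_ <- as_leaf_contour(cw)
  n <- nrow(c_)
  j <- c(2:n, 1)
  expect_gt(sum(c_$x * c_$y[j] - c_$x[j] * c_$y) / 2, 0)
  expect_error(as_leaf_contour(data.frame(x = c(0, 1), y = c(0, 1))),
               "at least 3")
  expect_error(polygon_area(data.frame(x = 1, y = 1)), "3 vertices")
})

test_that("resampling preserves geometry and is stable under repetition", {
  sq <- as_leaf_contour(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  r1 <- resample_contour(sq, 400)
  expect_equal(nrow(r1), 400)
  expect_equal(polygon_perimeter(r1), 4, tolerance = 1e-3)
  # second application moves no vertex more than one arclength step
  r2 <- resample_contour(r1, 400)
  step <- polygon_perimeter(r1) / 400
  d <- sqrt((r1$x - r2$x)^2 + (r1$y - r2$y)^2)
  expect_lt(max(d), step)
  expect_error(resample_contour(sq, 8), ">= 16")

  sim <- generate_leaf(leaf_params(n_teeth = 4, seed = 3))
  rl <- resample_contour(sim$contour, 1024)
  expect_lt(abs(polygon_area(rl) / sim$truth$true_area - 1), 0.005)
})

test_that("Gaussian contour smoothing is identity at sigma 0 and circle-preserving", {
  sim <- generate_leaf(leaf_params(n_teeth = 3, seed = 5))
  s0 <- smooth_contour(sim$contour, 0)
  expect_equal(s0$x, sim$contour$x)
  expect_equal(s0$y, sim$contour$y)
  expect_error(smooth_contour(sim$contour, -1), "non-negative")

  circ <- resample_contour(as_leaf_contour(regular_polygon(512, r = 100)), 512)
  sm <- smooth_contour(circ, 20)
  rr <- sqrt((sm$x - mean(sm$x))^2 + (sm$y - mean(sm$y))^2)
  expect_lt(diff(range(rr)) / mean(rr), 1e-6)
  expect_lt(mean(rr), 100)  # shrinks slightly

  # smoothing never exceeds the convex hull of the original
  rough <- resample_contour(sim$contour, 512)
  hull <- hull_area_perimeter(rough$x, rough$y)
  expect_lte(polygon_area(smooth_contour(rough, 30)), hull$area * (1 + 1e-9))
})

test_that("curvature is analytic on circles and integrates to one turn", {
  circ <- resample_contour(as_leaf_contour(regular_polygon(2048, r = 2)), 1024)
  cp <- curvature_profile(circ)
  expect_lt(max(abs(cp$kappa - 0.5)) / 0.5, 0.01)

  # straight portions of a rounded square are flat
  t <- seq(0, 2 * pi, length.out = 1025)[-1025]
  rsq <- sign(cos(t)) * abs(cos(t))^0.2  # superellipse-ish rounded square
  rsy <- sign(sin(t)) * abs(sin(t))^0.2
  c_ <- resample_contour(as_leaf_contour(data.frame(x = rsq, y = rsy)), 1024)
  cp2 <- curvature_profile(c_)
  corner_k <- max(cp2$kappa)
  flat <- abs(cp2$kappa)[order(abs(cp2$kappa))][1:100]
  expect_lt(max(flat), 1e-3 * corner_k)

  # turning-number identity
  h <- attr(cp2, "total_length") / nrow(c_)
  expect_equal(sum(cp2$kappa * h), 2 * pi, tolerance = 0.01)

  expect_error(curvature_profile(as_leaf_contour(
    data.frame(x = c(0, 5, 5.2, 0), y = c(0, 0, 1, 1.4)))), "resample")
})

test_that("area, perimeter and curvature transform correctly under scaling and rigid motion", {
  sim <- generate_leaf(leaf_params(n_teeth = 4, seed = 9))
  c_ <- resample_contour(sim$contour, 512)
  a0 <- polygon_area(c_); p0 <- polygon_perimeter(c_)
  k0 <- curvature_profile(c_)$kappa
  for (s in c(0.5, 3)) {
    cs <- as_leaf_contour(data.frame(x = s * c_$x, y = s * c_$y))
    expect_equal(polygon_area(cs), s^2 * a0, tolerance = 1e-9)
    expect_equal(polygon_perimeter(cs), s * p0, tolerance = 1e-9)
    # resampling commutes with scaling, so curvature scales exactly
    full <- as_leaf_contour(data.frame(x = s * sim$contour$x,
                                       y = s * sim$contour$y))
    csr <- resample_contour(full, 512)
    expect_equal(curvature_profile(csr)$kappa, k0 / s, tolerance = 1e-6)
  }
  set.seed(2)
  for (rep in 1:3) {
    cm <- as_leaf_contour(rigid_motion(c_, stats::runif(1, 0, 2 * pi),
                                       stats::runif(1, -500, 500),
                                       stats::runif(1, -500, 500)))
    expect_equal(polygon_area(cm), a0, tolerance = 1e-9)
    expect_equal(polygon_perimeter(cm), p0, tolerance = 1e-9)
  }
})

test_that("contour CSV dialect round-trips", {
  sim <- generate_leaf(leaf_params(n_teeth = 2, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contour_csv(sim$contour, path)
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, "x_um,y_um")
  back <- read_contour_csv(path)
  expect_equal(back$x, sim$contour$x)
  expect_equal(back$y, sim$contour$y)
})
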
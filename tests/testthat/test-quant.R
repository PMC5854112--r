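test_that("local background is exact on constructed images", {
  img <- matrix(100, 64, 64)
  bg <- local_background(img, c(32, 32), 10, 20)
  expect_equal(bg$background_level, 100)
  expect_equal(bg$spread, 0)

  # a bright disk inside r_in is excluded by the annulus
  img2 <- matrix(50, 64, 64)
  rr <- row(img2); cc <- col(img2)
  img2[(rr - 32)^2 + (cc - 32)^2 <= 8^2] <- 5000
  bg2 <- local_background(img2, c(32, 32), 12, 24)
  expect_equal(bg2$background_level, 50)

  expect_error(local_background(img, c(500, 500), 3, 6), "outside")
  expect_error(local_background(img, c(32, 32), 10, 5), "r_out > r_in")
})

test_that("background estimate tracks a synthetic gradient field", {
  fl <- generate_fluor_image(shape = c(128, 128),
    background = list(type = "gradient", level = 200, gx = 0.5, gy = -0.3),
    zone = list(center = c(64, 64), radius = 10, amplitude = 80),
    seed = 1)
  bg <- local_background(fl$image, c(64, 64), 15, 30)
  rr <- row(fl$image); cc <- col(fl$image)
  d <- sqrt((rr - 64)^2 + (cc - 64)^2)
  truth_mean <- mean(fl$truth$background_field[d >= 15 & d <= 30])
  expect_equal(bg$background_level, truth_mean, tolerance = 0.02)
})

test_that("the background estimator resists saturating outliers", {
  set.seed(1)
  img <- matrix(100 + rnorm(64 * 64, 0, 3), 64, 64)
  bg0 <- local_background(img, c(32, 32), 10, 20)
  img_bad <- img
  rr <- row(img); cc <- col(img)
  ann <- which(sqrt((rr - 32)^2 + (cc - 32)^2) >= 10 &
               sqrt((rr - 32)^2 + (cc - 32)^2) <= 20)
  img_bad[sample(ann, round(0.05 * length(ann)))] <- 65535
  bg1 <- local_background(img_bad, c(32, 32), 10, 20)
  expect_lt(abs(bg1$background_level - bg0$background_level), bg0$spread / 10)
})

test_that("zone segmentation is seeded, connected, and exact on clean disks", {
  img <- matrix(10, 64, 64)
  expect_equal(sum(segment_zone(img, c(32, 32), 10, 1, k = 3)), 0)

  fl <- generate_fluor_image(shape = c(128, 128),
    background = list(type = "flat", level = 100),
    zone = list(center = c(64, 64), radius = 12, amplitude = 50), seed = 2)
  q <- quantify_zone(fl$image, c(64, 64), zone_radius = 12)
  iou <- sum(q$zone_mask & fl$truth$zone_mask) /
    sum(q$zone_mask | fl$truth$zone_mask)
  expect_gte(iou, 0.95)

  # two disjoint blobs: the zone never leaks into the unseeded one
  img3 <- matrix(0, 64, 64)
  rr <- row(img3); cc <- col(img3)
  blobA <- (rr - 20)^2 + (cc - 20)^2 <= 6^2
  blobB <- (rr - 45)^2 + (cc - 45)^2 <= 6^2
  img3[blobA] <- 100; img3[blobB] <- 100
  mask <- segment_zone(img3, c(20, 20), 0, 1, k = 3)
  expect_true(all(!mask[blobB]))
  expect_true(all(mask[blobA]))
})

test_that("zone masks are bit-identical across repeated runs", {
  fl <- generate_fluor_image(shape = c(96, 96),
    background = list(type = "flat", level = 60),
    zone = list(center = c(48, 48), radius = 9, amplitude = 30),
    noise_sd = 4, seed = 3)
  m1 <- quantify_zone(fl$image, c(48, 48), zone_radius = 9)$zone_mask
  m2 <- quantify_zone(fl$image, c(48, 48), zone_radius = 9)$zone_mask
  expect_identical(m1, m2)
})

test_that("accumulated intensity is analytic on flat background plus disk", {
  fl <- generate_fluor_image(shape = c(128, 128),
    background = list(type = "flat", level = 40),
    zone = list(center = c(64, 64), radius = 14, amplitude = 25), seed = 4)
  acc <- accumulated_intensity(fl$image, fl$truth$zone_mask, 40)
  expect_equal(acc, 25 * sum(fl$truth$zone_mask), tolerance = 0.01)
  expect_equal(accumulated_intensity(fl$image,
                                     matrix(FALSE, 128, 128), 40), 0)
})

test_that("a global intensity shift leaves accumulated intensity unchanged", {
  fl <- generate_fluor_image(shape = c(128, 128),
    background = list(type = "gradient", level = 90, gx = 0.2, gy = 0.1),
    zone = list(center = c(64, 64), radius = 11, amplitude = 45),
    noise_sd = 2, seed = 5)
  q0 <- quantify_zone(fl$image, c(64, 64), zone_radius = 11)
  q1 <- quantify_zone(fl$image + 500, c(64, 64), zone_radius = 11)
  expect_lt(abs(q1$accumulated_intensity / q0$accumulated_intensity - 1), 0.01)
})

test_that("accumulated intensity responds linearly to zone amplitude", {
  amps <- seq(10, 80, length.out = 8)
  acc <- vapply(seq_along(amps), function(i) {
    fl <- generate_fluor_image(shape = c(128, 128),
      background = list(type = "flat", level = 70),
      zone = list(center = c(64, 64), radius = 12, amplitude = amps[i]),
      noise_sd = 2, seed = 100 + i)
    quantify_zone(fl$image, c(64, 64), zone_radius = 12)$accumulated_intensity
  }, numeric(1))
  fit <- stats::lm(acc ~ amps)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("nucleus detection recovers clean spots exactly", {
  set.seed(6)
  g <- expand.grid(row = seq(20, 100, by = 20), col = seq(20, 100, by = 20))
  g <- g[sample(nrow(g), 20), ]
  nuc <- data.frame(row = g$row + sample(-3:3, 20, TRUE),
                    col = g$col + sample(-3:3, 20, TRUE),
                    peak = seq(30, 600, length.out = 20))
  fl <- generate_fluor_image(shape = c(120, 120),
    background = list(type = "flat", level = 50),
    nuclei = nuc, spot_sigma = 2, noise_sd = 0, seed = 7)
  det <- detect_nuclei(fl$image, spot_sigma = 2, min_separation = 5)
  expect_equal(nrow(det), 20)
  for (k in seq_len(nrow(det))) {
    d <- sqrt((nuc$row - det$row[k])^2 + (nuc$col - det$col[k])^2)
    expect_lte(min(d), 1)
  }
  # truth-side intensities sorted descending follow the stated peaks
  tr <- fl$truth$nuclei
  expect_equal(order(tr$true_mean_intensity), order(tr$peak))

  expect_equal(nrow(detect_nuclei(matrix(5, 64, 64))), 0)
})

test_that("detections are invariant to a 90-degree rotation", {
  set.seed(8)
  nuc <- data.frame(row = sample(15:80, 10), col = sample(15:80, 10),
                    peak = seq(100, 500, length.out = 10))
  fl <- generate_fluor_image(shape = c(96, 96),
    background = list(type = "flat", level = 30),
    nuclei = nuc, spot_sigma = 2, noise_sd = 1, seed = 9)
  d0 <- detect_nuclei(fl$image, spot_sigma = 2, min_separation = 5)
  rot <- t(fl$image)[ncol(fl$image):1, ]      # 90-degree rotation
  d1 <- detect_nuclei(rot, spot_sigma = 2, min_separation = 5)
  expect_equal(nrow(d0), nrow(d1))
  # rotated coordinates: (r, c) -> (nr + 1 - c, r)
  for (k in seq_len(nrow(d0))) {
    rr <- 96 + 1 - d0$col[k]; cc <- d0$row[k]
    dd <- sqrt((d1$row - rr)^2 + (d1$col - cc)^2)
    expect_lte(min(dd), 1)
  }
})

test_that("top-k statistic is exact arithmetic with underpowering flagged", {
  nuc <- tibble::tibble(mean_intensity = 1:20)
  out <- top_k_mean(nuc, 12)
  expect_equal(out$mean_top_k, mean(9:20))
  expect_false(out$underpowered)

  out5 <- top_k_mean(tibble::tibble(mean_intensity = c(3, 1, 4, 1, 5)), 12)
  expect_equal(out5$mean_top_k, mean(c(3, 1, 4, 1, 5)))
  expect_true(out5$underpowered)

  expect_error(top_k_mean(tibble::tibble(mean_intensity = numeric(0))),
               "no nuclei")
})

test_that("top-12 of detected nuclei matches the truth statistic on noisy images", {
  set.seed(10)
  nuc <- data.frame(row = sample(20:105, 18), col = sample(20:105, 18),
                    peak = seq(150, 900, length.out = 18))
  fl <- generate_fluor_image(shape = c(128, 128),
    background = list(type = "flat", level = 80),
    nuclei = nuc, spot_sigma = 2, noise_sd = 5, seed = 11)
  det <- detect_nuclei(fl$image, spot_sigma = 2, min_separation = 5)
  got <- top_k_mean(det, 12)$mean_top_k
  want <- mean(sort(fl$truth$nuclei$true_mean_intensity,
                    decreasing = TRUE)[1:12])
  expect_lt(abs(got / want - 1), 0.03)
})

test_that("fluorescence TIFF i/o round-trips at 16-bit precision", {
  fl <- generate_fluor_image(shape = c(64, 64),
    background = list(type = "flat", level = 1000),
    zone = list(center = c(32, 32), radius = 8, amplitude = 2000),
    noise_sd = 10, seed = 12)
  path <- withr::local_tempfile(fileext = ".tif")
  write_fluor_tiff(fl$image, path)
  back <- read_fluor_tiff(path)
  expect_equal(dim(back), dim(fl$image))
  expect_lt(max(abs(back - fl$image)), 1)  # 16-bit quantization
})

test_that("fluorescence generator validates geometry and is deterministic", {
  expect_error(generate_fluor_image(shape = c(64, 64),
    zone = list(center = c(5, 5), radius = 10, amplitude = 1)), "outside")
  expect_error(generate_fluor_image(shape = c(64, 64),
    nuclei = data.frame(row = 100, col = 5, peak = 1)), "outside")
  a <- generate_fluor_image(shape = c(64, 64), noise_sd = 3, seed = 5)
  b <- generate_fluor_image(shape = c(64, 64), noise_sd = 3, seed = 5)
  expect_identical(a$image, b$image)
  # zero-amplitude zone, zero noise: image equals the background field
  z <- generate_fluor_image(shape = c(64, 64),
    background = list(type = "flat", level = 77),
    zone = list(center = c(32, 32), radius = 8, amplitude = 0), seed = 6)
  expect_identical(z$image, z$truth$background_field)
  expect_equal(z$truth$zone_total_signal, 0)
})
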
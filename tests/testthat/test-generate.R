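test_that("leaf_params validates its invariants", {
  expect_error(leaf_params(blade_length = -5), "positive")
  expect_error(leaf_params(tooth_height_frac = 1.2), "\\[0, 1\\)")
  expect_error(leaf_params(n_teeth = -1), ">= 0")
  expect_error(leaf_params(noise_amp = -1), ">= 0")
  expect_error(leaf_params(petiole_width = 600, blade_width = 400), "smaller")
})

test_that("toothless leaves have no tooth truth and a near-convex blade", {
  sim <- generate_leaf(leaf_params(n_teeth = 0, noise_amp = 0, seed = 1))
  expect_null(sim$truth$tooth_apices)
  expect_length(sim$truth$true_tooth_heights, 0)
  # the tooth-bearing margin band is convex: concavities exist only at the
  # basal flare and the acuminate tip, and no teeth are detectable
  rc <- resample_contour(sim$contour, 1024)
  kap <- curvature_profile(rc)$kappa
  ymax <- max(rc$y)
  mid <- rc$y > 0.25 * ymax & rc$y < 0.7 * ymax
  expect_true(all(kap[mid] > -0.5 * median(abs(kap))))
  expect_equal(nrow(detect_teeth(sim$contour)), 0)
})

test_that("truth bookkeeping matches construction", {
  sim <- generate_leaf(leaf_params(n_teeth = 5, seed = 4))
  expect_equal(nrow(sim$truth$tooth_apices), 10)
  expect_length(sim$truth$true_tooth_heights, 10)
  expect_equal(sim$truth$true_blade_length, 1000, tolerance = 1e-6)
  # apex/sinus landmarks lie on the contour
  expect_true(all(sim$truth$tooth_apices$vertex <= nrow(sim$contour)))
})

test_that("truth area and perimeter are self-consistent with independent oracles", {
  for (seed in 1:3) {
    sim <- generate_leaf(leaf_params(n_teeth = 4, noise_amp = 4, seed = seed))
    expect_equal(sim$truth$true_area,
                 earclip_area(sim$contour$x, sim$contour$y),
                 tolerance = 1e-9)
    n <- nrow(sim$contour)
    j <- c(2:n, 1)
    seg_sum <- sum(sqrt((sim$contour$x[j] - sim$contour$x)^2 +
                        (sim$contour$y[j] - sim$contour$y)^2))
    expect_equal(sim$truth$true_perimeter, seg_sum, tolerance = 1e-9)
    # tooth heights recomputable as apex-to-sinus-chord distances
    ap <- sim$truth$tooth_apices
    si <- sim$truth$sinus_points
    for (k in seq_len(nrow(ap))) {
      sp <- si[si$side == ap$side[k] & si$rank_from_base == ap$rank_from_base[k] &
                 si$flank == "prox", ]
      sd_ <- si[si$side == ap$side[k] & si$rank_from_base == ap$rank_from_base[k] &
                  si$flank == "dist", ]
      v1 <- c(sd_$x - sp$x, sd_$y - sp$y)
      d <- abs(v1[1] * (sp$y - ap$y[k]) - (sp$x - ap$x[k]) * v1[2]) /
        sqrt(sum(v1^2))
      expect_equal(sim$truth$true_tooth_heights[k], d, tolerance = 1e-6)
    }
  }
})

test_that("generation is bit-for-bit deterministic in params and seed", {
  p <- leaf_params(n_teeth = 3, noise_amp = 6, seed = 123)
  a <- generate_leaf(p)
  b <- generate_leaf(p)
  expect_identical(a$contour$x, b$contour$x)
  expect_identical(a$contour$y, b$contour$y)
  expect_identical(a$truth$true_tooth_heights, b$truth$true_tooth_heights)
  c_ <- generate_leaf(leaf_params(n_teeth = 3, noise_amp = 6, seed = 124))
  expect_false(identical(a$contour$x, c_$contour$x))
})

test_that("outline self-intersection is rejected with a diagnostic", {
  expect_error(
    generate_leaf(leaf_params(tooth_height_frac = 0.6,
                              tooth_width_frac = 0.3,
                              noise_amp = 150, seed = 1)),
    "self-intersect")
})

test_that("cohorts span the requested range and scale tooth heights", {
  base <- leaf_params(seed = 7)
  co <- generate_cohort(base, 50, blade_range = c(200, 5000), seed = 20)
  expect_equal(nrow(co), 50)
  expect_true(all(co$blade_length >= 200 & co$blade_length <= 5000))

  full <- generate_cohort(base, 8, blade_range = c(500, 1500),
                          genotype_tooth_scale = 1, seed = 3)
  half <- generate_cohort(base, 8, blade_range = c(500, 1500),
                          genotype_tooth_scale = 0.5, seed = 3)
  for (i in 1:8) {
    expect_true(all(half$truth[[i]]$true_tooth_heights <
                      full$truth[[i]]$true_tooth_heights))
  }
  expect_error(generate_cohort(base, 0), ">= 1")
  expect_error(generate_cohort(base, 5, blade_range = c(900, 300)),
               "increasing")
})

test_that("leaves and truth serialize to the CSV + JSON sidecar convention", {
  sim <- generate_leaf(leaf_params(n_teeth = 2, seed = 5))
  stem <- tempfile()
  write_leaf(sim, stem)
  back <- read_contour_csv(paste0(stem, ".csv"))
  expect_equal(nrow(back), nrow(sim$contour))
  tr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(tr$true_area, sim$truth$true_area, tolerance = 1e-12)
  expect_equal(nrow(tr$tooth_apices), 4)
  unlink(paste0(stem, c(".csv", ".json")))
})
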
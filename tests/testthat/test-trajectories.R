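test_that("degree-1 local regression reproduces linear data exactly", {
  set.seed(3)
  d <- data.frame(blade_length = sort(stats::runif(40, 100, 900)))
  d$value <- 2 * d$blade_length + 1
  for (span in c(0.3, 0.75, 1)) {
    f <- loess_fit(d, span = span, degree = 1)
    expect_lt(max(abs(f$curve$fitted - (2 * f$curve$grid + 1))), 1e-9)
  }
  # constant data
  d$value <- 7
  f <- loess_fit(d, span = 0.5)
  expect_lt(max(abs(f$curve$fitted - 7)), 1e-9)
})

test_that("degree-2 smoothing beats the raw points on a noisy quadratic", {
  set.seed(42)
  x <- sort(stats::runif(120, -2, 2))
  truth <- 3 + x - 1.5 * x^2
  y <- truth + stats::rnorm(120, 0, 0.4)
  f <- loess_fit(data.frame(blade_length = x, value = y),
                 span = 0.5, degree = 2, grid = x)
  rmse_fit <- sqrt(mean((f$curve$fitted - truth)^2))
  rmse_raw <- sqrt(mean((y - truth)^2))
  expect_lt(rmse_fit, rmse_raw)
})

test_that("local regression is invariant to row order and dataset duplication", {
  set.seed(8)
  d <- data.frame(blade_length = stats::runif(30, 0, 10))
  d$value <- sin(d$blade_length) + stats::rnorm(30, 0, 0.1)
  g <- seq(1, 9, length.out = 21)
  f1 <- loess_fit(d, span = 0.6, grid = g)
  f2 <- loess_fit(d[sample(30), ], span = 0.6, grid = g)
  expect_equal(f1$curve$fitted, f2$curve$fitted, tolerance = 1e-12)
  f3 <- loess_fit(rbind(d, d), span = 0.6, grid = g)
  expect_equal(f1$curve$fitted, f3$curve$fitted, tolerance = 1e-9)
})

test_that("the trajectory fit agrees with stats::loess as an independent reference", {
  set.seed(19)
  d <- data.frame(blade_length = sort(stats::runif(80, 0, 100)))
  d$value <- 0.05 * d$blade_length + sin(d$blade_length / 8) +
    stats::rnorm(80, 0, 0.2)
  g <- seq(10, 90, length.out = 15)
  mine <- loess_fit(d, span = 0.75, degree = 1, grid = g)$curve$fitted
  ref <- stats::predict(
    stats::loess(value ~ blade_length, data = d, span = 0.75, degree = 1,
                 family = "gaussian", surface = "direct"),
    newdata = data.frame(blade_length = g))
  expect_equal(mine, unname(ref), tolerance = 0.01)
})

test_that("grid points with too few support points are flagged, not fabricated", {
  d <- data.frame(blade_length = c(1, 1, 1, 10), value = c(2, 2, 2, 5))
  f <- loess_fit(d, span = 0.5, degree = 1, grid = c(1, 5.5, 10))
  expect_true(any(is.na(f$curve$fitted)))
  expect_true(all(f$curve$support >= 0))
})

test_that("blade-length-class t-tests follow the pooled-variance formula", {
  d <- data.frame(genotype = rep(c("A", "B"), each = 5),
                  blade_length = 300, value = c(1:5, 2:6))
  out <- bin_and_test(d, class_edges = c(200, 400))
  expect_equal(out$t, -1)
  # closed-form pooled t-test p-value
  expect_equal(out$p, 2 * pt(-1, df = 8))
  expect_equal(out$n_A, 5)

  # identical samples: t = 0, p = 1
  d2 <- data.frame(genotype = rep(c("A", "B"), each = 4),
                   blade_length = 250, value = rep(c(1, 2, 3, 4), 2))
  out2 <- bin_and_test(d2, class_edges = c(200, 400))
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
})

test_that("swapping groups flips t and preserves p", {
  set.seed(4)
  d <- data.frame(genotype = rep(c("A", "B"), each = 20),
                  blade_length = stats::runif(40, 200, 800),
                  value = stats::rnorm(40, rep(c(5, 6), each = 20)))
  out <- bin_and_test(d)
  d2 <- d
  d2$genotype <- ifelse(d$genotype == "A", "Z", "A")  # swap level order
  out2 <- bin_and_test(d2)
  ok <- out$testable & out2$testable
  expect_equal(out2$t[ok], -out$t[ok])
  expect_equal(out2$p[ok], out$p[ok])
})

test_that("underpopulated classes are reported untestable, never dropped", {
  d <- data.frame(genotype = c("A", "A", "A", "B", "B", "B"),
                  blade_length = c(250, 260, 450, 250, 260, 270),
                  value = 1:6)
  out <- bin_and_test(d, class_edges = c(200, 400, 600, 800))
  expect_equal(nrow(out), 3)
  expect_true(out$testable[1])
  expect_false(out$testable[2])  # only one A in 400-600
  expect_false(out$testable[3])  # empty class still reported
  expect_true(is.na(out$p[2]))
})

test_that("phenotype frequencies normalize within genotype", {
  counts <- data.frame(
    genotype = c("wt", "wt", "mutant", "mutant", "mutant"),
    category = c("none", "heart", "none", "heart", "cup"),
    count = c(90, 10, 40, 30, 30))
  f <- phenotype_frequencies(counts)
  expect_equal(f$frequency[f$genotype == "wt"], c(0.9, 0.1))
  sums <- tapply(f$frequency, f$genotype, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  one <- phenotype_frequencies(data.frame(genotype = "x", category = "only",
                                          count = 5))
  expect_equal(one$frequency, 1)
  expect_error(phenotype_frequencies(
    data.frame(genotype = "x", category = "a", count = 0)), "zero total")
})
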
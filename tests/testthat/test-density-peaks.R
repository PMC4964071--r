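test_that("kernel density estimate recovers a standard normal density", {
  set.seed(1)
  x <- stats::rnorm(10000)
  d <- estimate_density(x)
  expect_length(d$grid, 512)
  # equally spaced grid
  expect_equal(max(abs(diff(diff(d$grid)))), 0, tolerance = 1e-9)
  expect_true(all(d$density >= 0))
  # trapezoidal integral ~ 1
  integral <- sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_gt(integral, 0.98)
  expect_lt(integral, 1.02)
  # density near 0 close to 1/sqrt(2 pi)
  at0 <- d$density[which.min(abs(d$grid))]
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.1)
})

test_that("density estimation rejects insufficient or degenerate input", {
  expect_error(estimate_density(1:5), "at least 10")
  expect_error(estimate_density(rep(2, 50)), "zero spread")
  expect_error(estimate_density(stats::rnorm(100), bandwidth = -1),
               "bandwidth")
})

test_that("a bimodal mixture shows a density dip at the midpoint", {
  set.seed(2)
  x <- c(stats::rnorm(10000, -3), stats::rnorm(10000, 3))
  d <- estimate_density(x)
  at <- function(v) d$density[which.min(abs(d$grid - v))]
  expect_lt(at(0), at(-3))
  expect_lt(at(0), at(3))
})

test_that("peak detection separates well-separated modes and partitions the
           grid span", {
  set.seed(3)
  x <- c(stats::rnorm(10000, -3), stats::rnorm(10000, 3))
  d <- estimate_density(x)
  pk <- detect_peaks(d)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$mode, c(-3, 3), tolerance = 0.3)
  # boundary at the density minimum, near 0 for a symmetric mixture
  expect_lt(abs(pk$hi[1]), 0.5)
  expect_equal(pk$hi[1], pk$lo[2])
  expect_equal(pk$lo[1], d$grid[1])
  expect_equal(pk$hi[2], d$grid[512])
  expect_true(all(pk$lo < pk$mode & pk$mode < pk$hi))
})

test_that("a unimodal curve yields one peak spanning the whole grid", {
  set.seed(4)
  d <- estimate_density(stats::rnorm(5000))
  pk <- detect_peaks(d)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$lo, d$grid[1])
  expect_equal(pk$hi, d$grid[512])
})

test_that("sub-threshold bumps are filtered by height and prominence", {
  g <- seq(-5, 5, length.out = 512)
  main <- stats::dnorm(g)
  # a bump of height 0.5% of the maximum, far in the tail
  bump <- 0.005 * stats::dnorm(0) * exp(-((g - 4) / 0.1)^2)
  curve <- structure(list(grid = g, density = main + bump, bandwidth = 0.1),
                     class = "density_curve")
  pk <- detect_peaks(curve, min_height_frac = 0.01)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mode, 0, tolerance = 0.02)
  # raised above the height threshold but still low prominence: a shoulder
  # bump of 3% height passes the 1% height filter yet fails the 5%
  # prominence filter when riding on the main peak's flank
  shoulder <- 0.03 * stats::dnorm(0) * exp(-((g - 1.2) / 0.15)^2)
  curve2 <- structure(list(grid = g, density = main + shoulder,
                           bandwidth = 0.1),
                      class = "density_curve")
  expect_equal(nrow(detect_peaks(curve2)), 1)
})

test_that("peak detection commutes with affine rescaling of the data", {
  set.seed(5)
  x <- c(stats::rnorm(8000, -2, 0.5), stats::rnorm(8000, 2, 0.5))
  a <- 3.7; b <- -11
  d1 <- estimate_density(x)
  d2 <- estimate_density(a * x + b)
  p1 <- detect_peaks(d1)
  p2 <- detect_peaks(d2)
  expect_equal(nrow(p1), nrow(p2))
  step <- diff(d2$grid[1:2])
  expect_equal(p2$mode, a * p1$mode + b, tolerance = 2 * step)
  expect_equal(p2$hi[1], a * p1$hi[1] + b, tolerance = 2 * step)
})

test_that("peak collection pools one peak per unimodal sample", {
  ds <- simulate_fc_dataset(n_samples = 3,
                            populations = data.frame(weight = 1, mu_t = 2,
                                                     sigma_t = 0.3),
                            true_cofactor = 50, events_per_sample = 3000,
                            seed = 6)
  ps <- collect_peaks(ds, "FL1", 50)
  expect_s3_class(ps, "peak_set")
  expect_equal(ps$m, 3)
  expect_true(ps$valid)
  expect_setequal(ps$peaks$sample_id, c("sim01", "sim02", "sim03"))
})

test_that("event assignment to peak regions is an exhaustive partition", {
  ds <- simulate_fc_dataset(n_samples = 1, true_cofactor = 100,
                            events_per_sample = 10000, seed = 7)
  ps <- collect_peaks(ds, "FL1", 100, min_events = 50)
  expect_equal(ps$m, 2)
  expect_equal(ps$n, 10000)
  expect_equal(sum(ps$peaks$n), 10000)
  # pooled variance lies between the extreme peak variances
  expect_gte(ps$pooled_var, min(ps$peaks$var))
  expect_lte(ps$pooled_var, max(ps$peaks$var))
  expect_equal(ps$pooled_var,
               sum((ps$peaks$n - 1) * ps$peaks$var) / (ps$n - ps$m))
})

test_that("undersized peaks are dropped with a warning", {
  set.seed(8)
  # 1970 events in the main population, 30 in a far-away satellite
  z <- c(stats::rnorm(1970, 10, 0.5), stats::rnorm(30, 60, 0.5))
  s <- fc_sample(matrix(z, ncol = 1), channels = "FL1", sample_id = "s1")
  expect_warning(ps <- collect_peaks(list(s), "FL1", 1, min_events = 50),
                 "dropped")
  expect_equal(ps$m, 1)
  expect_lt(abs(ps$peaks$mode - asinh(10)), 0.5)
})

test_that("peak collection errors when the channel is missing", {
  ds <- simulate_fc_dataset(n_samples = 2, events_per_sample = 1000,
                            seed = 9)
  expect_error(collect_peaks(ds, "CD4", 10), "CD4")
})
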
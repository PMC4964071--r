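test_that("interval minimizer solves smooth, monotone and step objectives", {
  # quadratic
  r <- minimize_interval(function(c) (c - 10)^2, 5, 20, tol = 1e-4)
  expect_equal(r$minimum, 10, tolerance = 1e-3)
  expect_equal(r$value, (r$minimum - 10)^2)
  # monotone decreasing: minimizer adjacent to the upper endpoint
  r <- minimize_interval(function(c) -c, 1, 2, tol = 1e-4)
  expect_equal(r$minimum, 2, tolerance = 1e-3)
  # piecewise constant with a single lower step in the middle; brute-force
  # grid evaluation of the same function is the oracle
  f <- function(c) ifelse(c > 4 & c < 6, 1, 2)
  grid <- seq(1, 10, length.out = 2000)
  oracle <- grid[which.min(f(grid))]
  expect_true(oracle > 4 && oracle < 6)
  r <- minimize_interval(f, 1, 10, tol = 1e-4)
  expect_gt(r$minimum, 4)
  expect_lt(r$minimum, 6)
  expect_equal(r$value, 1)
})

test_that("the homogeneity objective dips at the true cofactor and is
           deterministic", {
  c0 <- exp(4)
  ds <- simulate_fc_dataset(true_cofactor = c0, events_per_sample = 5000,
                            seed = 21)
  b0 <- vs_objective(ds, "FL1", c0)
  expect_lt(b0, vs_objective(ds, "FL1", c0 * exp(3)))
  expect_lt(b0, vs_objective(ds, "FL1", c0 * exp(-3)))
  expect_identical(b0, vs_objective(ds, "FL1", c0))
})

test_that("a single unimodal sample gives the undefined-statistic sentinel", {
  ds <- simulate_fc_dataset(n_samples = 1,
                            populations = data.frame(weight = 1, mu_t = 2,
                                                     sigma_t = 0.3),
                            true_cofactor = 50, events_per_sample = 2000,
                            seed = 22)
  expect_identical(vs_objective(ds, "FL1", 50), Inf)
  expect_error(optimize_cofactor(ds, "FL1", c_low = 3, c_high = 5),
               "no cofactor yielded")
})

test_that("the interval scan recovers a known cofactor and dominates its
           own trace", {
  c0 <- exp(4.5)
  ds <- simulate_fc_dataset(true_cofactor = c0, events_per_sample = 5000,
                            seed = 23)
  scan <- optimize_cofactor(ds, "FL1")
  expect_s3_class(scan, "cofactor_scan")
  expect_equal(scan$k, 12)
  expect_lte(abs(log(scan$c_star) - 4.5), 0.5)
  expect_gte(scan$c_star, exp(-2))
  expect_lte(scan$c_star, exp(10))
  # the returned optimum is the best evaluation seen anywhere
  expect_equal(scan$B_star, min(scan$interval_optima$B))
  expect_lte(scan$B_star, min(scan$trace$B))
  # bit-identical rerun (determinism of the whole scan)
  scan2 <- optimize_cofactor(ds, "FL1")
  expect_identical(scan$trace, scan2$trace)
  expect_identical(scan$c_star, scan2$c_star)
})

test_that("non-integer bounds produce a final partial log-interval", {
  c0 <- exp(4.2)
  ds <- simulate_fc_dataset(true_cofactor = c0, events_per_sample = 3000,
                            seed = 24)
  scan <- optimize_cofactor(ds, "FL1", c_low = 3.5, c_high = 5.8)
  expect_equal(scan$k, 3)
  expect_equal(scan$interval_optima$lo[1], exp(3.5))
  expect_equal(scan$interval_optima$hi[3], exp(5.8))
  expect_equal(scan$interval_optima$hi[2], exp(5.5))
})

test_that("dataset stabilization recovers per-channel cofactors
           independently and skips scatter channels", {
  ds <- make_two_channel_dataset(exp(3), exp(6), events = 5000, seed = 25)
  expect_warning(
    res <- stabilize_dataset(ds, c("FL1", "FL2", "FSC-A"),
                             c_low = 1, c_high = 8),
    "scatter")
  expect_setequal(res$summary$channel, c("FL1", "FL2"))
  expect_lte(abs(log(res$cofactors$FL1$c_star) - 3), 0.5)
  expect_lte(abs(log(res$cofactors$FL2$c_star) - 6), 0.5)
  # the same cofactor is applied to a channel in every sample, and the
  # transformed values are exactly asinh(z / c_star)
  for (j in seq_along(ds)) {
    expect_equal(res$transformed[[j]]$exprs[, "FL1"],
                 asinh_transform(ds[[j]]$exprs[, "FL1"],
                                 res$cofactors$FL1$c_star))
  }
  # re-evaluating the objective at c_star reproduces B_star
  expect_equal(vs_objective(ds, "FL1", res$cofactors$FL1$c_star),
               res$cofactors$FL1$B_star)
})

test_that("stabilization removes the mean-variance dependence of raw peaks", {
  ds <- simulate_fc_dataset(
    n_samples = 4,
    populations = data.frame(weight = c(0.3, 0.3, 0.2, 0.2),
                             mu_t = c(0.8, 2.2, 3.6, 5.0),
                             sigma_t = rep(0.3, 4)),
    true_cofactor = exp(4), events_per_sample = 8000, seed = 26)
  scan <- optimize_cofactor(ds, "FL1", c_low = 2, c_high = 6)
  pk <- raw_peak_stats(ds, "FL1", scan$c_star)
  rho_before <- stats::cor(rank(pk$raw_mu), pk$raw_var, method = "spearman")
  rho_after <- stats::cor(rank(pk$mu), pk$var, method = "spearman")
  expect_gt(rho_before, 0.8)
  expect_lt(abs(rho_after), abs(rho_before))
})
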
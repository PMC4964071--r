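test_that("gene groups do the bookkeeping of one group per gene", {
  set.seed(31)
  mat <- expression_matrix(matrix(stats::rnorm(400, 100, 10), 100, 4))
  gg <- gene_groups(mat, 10)
  expect_s3_class(gg, "peak_set")
  expect_equal(gg$m, 100)
  expect_equal(gg$n, 400)
  expect_true(all(gg$peaks$n == 4))
  # hand-computed group mean: row (100, 400) at c = 100
  m2 <- expression_matrix(matrix(c(100, 400), 1, 2),
                          gene_ids = "g1", sample_ids = c("a", "b"))
  gg2 <- gene_groups(m2, 100)
  expect_equal(gg2$peaks$mu, (asinh(1) + asinh(4)) / 2, tolerance = 1e-12)
  expect_equal(gg2$peaks$mu, 1.488, tolerance = 1e-3)
})

test_that("zero-variance genes are dropped and an all-constant matrix is
           invalid", {
  mat <- expression_matrix(matrix(rep(c(5, 7, 9), each = 4), 3, 4,
                                  byrow = TRUE))
  expect_warning(gg <- gene_groups(mat, 1), "near-zero variance")
  expect_equal(gg$m, 0)
  expect_false(gg$valid)
})

test_that("Bartlett over gene groups is invariant to gene order", {
  set.seed(32)
  v <- matrix(stats::rnorm(600, 50, 20), 100, 6)
  mat <- expression_matrix(v)
  perm <- sample(100)
  matp <- expression_matrix(v[perm, , drop = FALSE],
                            gene_ids = paste0("g", perm))
  expect_equal(bartlett_statistic(gene_groups(mat, 30)),
               bartlett_statistic(gene_groups(matp, 30)),
               tolerance = 1e-12)
})

test_that("equal-variance rows in the linear regime give a flat, near-zero
           scan", {
  set.seed(33)
  delta <- stats::rnorm(6)
  delta <- (delta - mean(delta)) / stats::sd(delta)  # exact unit variance
  v <- outer(seq(2, 4, length.out = 50), rep(1, 6)) + 0.01 *
    matrix(delta, 50, 6, byrow = TRUE)
  mat <- expression_matrix(v)
  # for c >> max|x| the transform is linear, so equal variances persist
  b <- vapply(c(exp(5), exp(7), exp(9)), function(cf)
    bartlett_statistic(gene_groups(mat, cf)), 1)
  expect_true(all(b < 1e-3))
  expect_lt(max(b) - min(b), 1e-3)
})

test_that("the microarray scan recovers the constructed cofactor and is
           scale-equivariant", {
  mat <- simulate_expression_matrix(m_genes = 500, n_samples = 6,
                                    true_cofactor = exp(5), seed = 34)
  scan <- optimize_cofactor_microarray(mat, c_low = 2, c_high = 8)
  expect_lte(abs(log(scan$c_star) - 5), 0.5)
  # doubling every value doubles the selected cofactor
  mat2 <- expression_matrix(2 * mat$values, gene_ids = mat$gene_ids,
                            sample_ids = mat$sample_ids)
  scan2 <- optimize_cofactor_microarray(mat2, c_low = 2, c_high = 8)
  expect_equal(scan2$c_star / scan$c_star, 2, tolerance = 0.05)
})

test_that("mean-sd profile ranks are a permutation and flag
           heteroskedasticity", {
  set.seed(35)
  # homoskedastic: flat running-median curve
  hom <- expression_matrix(matrix(stats::rnorm(2000 * 6, mean = 50), 2000, 6))
  prof <- mean_sd_profile(hom)
  expect_setequal(prof$rank_of_mean, seq_len(2000))
  expect_lt(max(prof$running_median_sd) / min(prof$running_median_sd), 1.5)
  # sd proportional to mean: running medians increase across rank deciles
  mu <- seq(10, 100, length.out = 2000)
  het <- expression_matrix(mu + matrix(stats::rnorm(2000 * 6), 2000, 6) *
                             (0.1 * mu))
  prof2 <- mean_sd_profile(het)
  dec <- split(prof2$running_median_sd,
               cut(prof2$rank_of_mean, breaks = 10))
  expect_true(all(diff(vapply(dec, stats::median, 1)) > 0))
})

test_that("expression matrices round-trip through delimited text", {
  set.seed(36)
  mat <- expression_matrix(matrix(stats::rnorm(60, 100, 30), 10, 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(mat, path)
  back <- read_expression_matrix(path)
  expect_equal(back$gene_ids, mat$gene_ids)
  expect_equal(back$sample_ids, mat$sample_ids)
  expect_equal(unname(back$values), unname(mat$values), tolerance = 1e-10)
})

test_that("malformed matrix files fail with context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\ts1\ts2", path)  # header only, no rows
  expect_error(read_expression_matrix(path), "malformed")
  writeLines(c("gene\ts1\ts2", "g1\t1.0\tnot_a_number"), path)
  expect_error(read_expression_matrix(path), "not numeric")
  # rows with missing values are excluded with a warning
  expect_warning(
    em <- expression_matrix(rbind(c(1, 2), c(NA, 3), c(4, 5))),
    "non-finite")
  expect_equal(nrow(em$values), 2)
})
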
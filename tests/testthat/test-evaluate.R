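test_that("SUV conversion follows dose-per-weight normalization", {
  meta <- scan_meta(370, 74)
  # 5 kBq/mL against 370 MBq in 74 kg: exactly SUV 1
  expect_equal(to_suv(5, meta), 1)
  expect_equal(to_suv(0, meta), 0)
  # linearity: doubling the dose halves SUV everywhere
  arr <- array(runif(16), c(4, 4))
  expect_equal(to_suv(arr, scan_meta(740, 74)), to_suv(arr, meta) / 2)
  expect_error(scan_meta(0, 70), "dose")
  expect_error(scan_meta(370, -1), "weight")
})

test_that("VOI masks equal brute-force membership counts", {
  g <- tiny_grid(64)
  for (spec in list(list(c(0, 0), 12), list(c(-31, 17), 21),
                    list(c(10.2, 3.3), 9))) {
    m <- voi_mask(spec[[1]], spec[[2]], g)
    expect_identical(m, brute_force_mask(spec[[1]], spec[[2]], g))
  }
  expect_error(voi_mask(c(0, 0), 1e6, g), "outside")
  # a grid-filling VOI includes every voxel the brute-force rule includes
  big <- voi_mask(c(0, 0), 190, g)
  expect_identical(big, brute_force_mask(c(0, 0), 190, g))
})

test_that("SUV Error Ratio and Lesion Error Ratio are plain ratios with
           guards", {
  expect_equal(suv_error_ratio(1, 1), 1)
  expect_equal(suv_error_ratio(0.9, 1), 0.9)
  expect_error(suv_error_ratio(1, 0), "degenerate")
  expect_equal(lesion_error_ratio(0.88, 0.88), 1)
  expect_error(lesion_error_ratio(1, 0), "degenerate")
})

test_that("voxel-wise difference percentages follow the defining formula", {
  a <- array(1:16, c(4, 4))
  m <- array(TRUE, c(4, 4))
  expect_true(all(voxel_diff_percent(a, a, m) == 0))
  expect_true(all(abs(voxel_diff_percent(0.9 * a, a, m) + 10) < 1e-12))
  expect_true(all(abs(voxel_diff_percent(1.05 * a, a, m) - 5) < 1e-12))
  # floor exclusion is counted
  b <- a; b[1, 1] <- 0
  d <- voxel_diff_percent(a, b, m)
  expect_equal(attr(d, "n_excluded"), 1)
  expect_length(d, 15)
  expect_error(voxel_diff_percent(a, 0 * a, m), "below floor")
})

test_that("difference statistics decompose RMSE into bias and spread", {
  st <- diff_stats(c(-5, -5, -5))
  expect_equal(st$mu_pct, -5)
  expect_equal(st$sigma_pct, 0)
  expect_equal(st$rmse_pct, 5)
  expect_equal(st$max_abs_pct, 5)
  expect_equal(st$diff_max_pct, -5)
  set.seed(42)
  for (i in 1:20) {
    st <- diff_stats(rnorm(50, mean = runif(1, -10, 10), sd = runif(1, 0, 5)))
    expect_equal(st$rmse_pct^2, st$mu_pct^2 + st$sigma_pct^2,
                 tolerance = 1e-12)
    expect_gte(st$max_abs_pct, abs(st$mu_pct))
  }
  expect_error(diff_stats(numeric(0)), "empty")
})

test_that("Bland-Altman limits are mean +/- 1.96 sample SD", {
  ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  same <- bland_altman(c(0.9, 1.0, 1.1, 1.2), c(0.9, 1.0, 1.1, 1.2))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "3 pairs")
  # large-sample normal coverage: about 95% of pairs inside the limits
  set.seed(7)
  d <- rnorm(400)
  ba2 <- bland_altman(d, numeric(400))
  expect_gte(ba2$fraction_within, 0.93)
})

test_that("linear trend recovers exact lines and flags degenerate input", {
  x <- 1:10
  tr <- linear_trend(x, 2 * x + 1)
  expect_equal(tr$slope, 2)
  expect_equal(tr$r_squared, 1)
  flat <- linear_trend(x, rep(3, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(linear_trend(rep(1, 5), 1:5), "constant")
})

test_that("VOI bone fraction counts labelled voxels", {
  g <- tiny_grid(32)
  lab <- matrix(2L, 32, 32)
  m <- voi_mask(c(0, 0), 15, g)
  expect_equal(voi_bone_fraction(m, lab), 0)
  lab[] <- 3L
  expect_equal(voi_bone_fraction(m, lab), 1)
  lab[1:16, ] <- 2L
  expect_equal(voi_bone_fraction(m, lab), mean(lab[m] == 3L))
})
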
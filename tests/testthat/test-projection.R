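test_that("forward projection is linear and zero on zero volumes", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 24)
  expect_true(all(forward_project(array(0, c(32, 32)), g, geom)$values == 0))
  set.seed(1)
  a <- array(runif(32 * 32), c(32, 32))
  b <- array(runif(32 * 32), c(32, 32))
  lhs <- forward_project(2.5 * a - 0.5 * b, g, geom)$values
  rhs <- 2.5 * forward_project(a, g, geom)$values -
    0.5 * forward_project(b, g, geom)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("per-angle bin sums of a disc equal the analytic disc integral", {
  g <- tiny_grid(64)
  geom <- tiny_geom(g, 48)
  vol <- disc_volume(g, radius_mm = 60, value = 2)
  # oracle: every angular view of a compact source integrates to value x area,
  # where the discrete area is the rasterized disc's voxel area
  total <- 2 * sum(vol > 0) * voxel_volume_mm(g)
  sums <- rowSums(forward_project(vol, g, geom)$values) *
    geom$radial_spacing_mm
  expect_true(all(abs(sums - total) / total < 0.01))
})

test_that("a point source traces the analytic sinusoid locus", {
  g <- tiny_grid(64)
  geom <- tiny_geom(g, 48)
  # off-centre point at world (d cos phi, d sin phi)
  ctr <- c(30, -45)
  d <- sqrt(sum(ctr^2))
  phi <- atan2(ctr[2], ctr[1])
  vol <- array(0, c(64, 64))
  idx <- round(world_to_index(g, ctr))
  vol[idx[1], idx[2]] <- 1
  w <- index_to_world(g, idx)  # actual voxel-centre position
  d <- sqrt(sum(w^2)); phi <- atan2(w[2], w[1])
  sino <- forward_project(vol, g, geom)$values
  r_pred <- d * cos(geom$angles_deg * pi / 180 - phi)
  k_pred <- r_pred / geom$radial_spacing_mm + (geom$n_radial_bins + 1) / 2
  k_obs <- apply(sino, 1, which.max)
  expect_true(all(abs(k_obs - k_pred) <= 1))
})

test_that("attenuation factors are exp(-line integral) in (0, 1]", {
  g <- voxel_grid(c(128, 128), 2)   # 256 mm FOV for a 200 mm disc
  geom <- default_geometry(g, 32)
  expect_true(all(attenuation_factors(
    mu_map(g, array(0, c(128, 128))), geom)$values == 1))
  muv <- disc_volume(g, radius_mm = 100, value = 0.0975)
  af <- attenuation_factors(mu_map(g, muv), geom)
  ctr <- (geom$n_radial_bins + 1) / 2
  # closed form: exp(-0.0975/cm x 20 cm) through the disc centre
  expect_equal(af$values[1, ctr], exp(-1.95), tolerance = 0.03)
  expect_true(all(af$values > 0 & af$values <= 1))
  # monotonicity: more attenuating medium, smaller factors everywhere
  af2 <- attenuation_factors(mu_map(g, 2 * muv), geom)
  expect_true(all(af2$values <= af$values))
})

test_that("simulated acquisitions obey the Poisson model", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 24)
  vol <- disc_volume(g, radius_mm = 30, value = 5)
  lam <- simulate_acquisition(vol, g, geom = geom, count_scale = 0.4,
                              noise = FALSE)
  expect_equal(lam$values, 0.4 * forward_project(vol, g, geom)$values)
  # fixed seed reproducibility
  y1 <- simulate_acquisition(vol, g, geom = geom, count_scale = 0.4,
                             seed = 9, noise = TRUE)
  y2 <- simulate_acquisition(vol, g, geom = geom, count_scale = 0.4,
                             seed = 9, noise = TRUE)
  expect_identical(y1$values, y2$values)
  expect_true(all(y1$values == round(y1$values) & y1$values >= 0))
  # Monte-Carlo oracle: mean of 200 draws matches lambda within 3 SE for
  # at least 99% of informative bins, and variance tracks the mean
  draws <- vapply(seq_len(200), function(s) {
    as.vector(simulate_acquisition(vol, g, geom = geom, count_scale = 0.4,
                                   seed = 1000 + s, noise = TRUE)$values)
  }, numeric(length(lam$values)))
  lamv <- as.vector(lam$values)
  keep <- lamv > 0.5
  se <- sqrt(lamv[keep] / 200)
  frac_ok <- mean(abs(rowMeans(draws)[keep] - lamv[keep]) <= 3 * se)
  expect_gte(frac_ok, 0.99)
  v <- apply(draws[keep, ], 1, var)
  expect_equal(mean(v / lamv[keep]), 1, tolerance = 0.05)
})

test_that("sinogram addition respects kind, geometry and linearity", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 24)
  a <- disc_volume(g, 20, 3)
  b <- disc_volume(g, 30, 1)
  sa <- simulate_acquisition(a, g, geom = geom, noise = FALSE)
  sb <- simulate_acquisition(b, g, geom = geom, noise = FALSE)
  zero <- sinogram(geom, matrix(0, geom$n_angles, geom$n_radial_bins),
                   "expected_counts", scale = sa$scale)
  expect_equal(add_sinograms(sa, zero)$values, sa$values)
  # sum of expected-count sinograms == acquisition of the summed activities
  sab <- simulate_acquisition(a + b, g, geom = geom, noise = FALSE)
  expect_equal(add_sinograms(sa, sb)$values, sab$values, tolerance = 1e-12)
  ya <- simulate_acquisition(a, g, geom = geom, seed = 1, noise = TRUE)
  yb <- simulate_acquisition(b, g, geom = geom, seed = 2, noise = TRUE)
  ysum <- add_sinograms(ya, yb)
  expect_true(all(ysum$values == round(ysum$values)))
  expect_error(add_sinograms(ya, sb), "kind")
  other <- system_geometry(24, geom$n_radial_bins + 2, geom$radial_spacing_mm)
  expect_error(
    add_sinograms(ya, sinogram(other, matrix(0, 24, geom$n_radial_bins + 2),
                               "counts")),
    "geometry")
})

test_that("geometry validation catches undersized radial coverage", {
  g <- tiny_grid(64)
  small <- system_geometry(24, 10, 3)
  expect_error(forward_project(array(1, c(64, 64)), g, small), "diagonal")
  expect_error(system_geometry(8, 91, 3), "n_angles")
  expect_error(normalization_map(tiny_geom(g), 3), "0, 2")
})
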
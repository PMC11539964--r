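test_that("OSEM with one subset reproduces the classical MLEM iteration", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 24)
  ph <- disc_volume(g, 30, 4) + disc_volume(g, 9, 10, center = c(12, -6))
  muv <- mu_map(g, disc_volume(g, 30, 0.0975))
  y <- simulate_acquisition(ph, g, mu = muv, geom = geom, count_scale = 0.5,
                            seed = 3, noise = TRUE)
  for (iters in c(1, 3)) {
    ref <- reference_mlem(y, g, muv, iters, 0.5)
    got <- osem(y, recon_params(mu_map = muv, iterations = iters,
                                subsets = 1, psf_fwhm_mm = 0), g)
    expect_equal(got$activity_kbq_ml, ref, tolerance = 1e-10)
  }
})

test_that("noiseless uniform-disc reconstruction conserves total activity", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 32)
  vol <- disc_volume(g, 30, 5)
  lam <- simulate_acquisition(vol, g, geom = geom, count_scale = 1,
                              noise = FALSE)
  rec <- osem(lam, recon_params(iterations = 10, subsets = 1,
                                psf_fwhm_mm = 0), g)
  expect_equal(sum(rec$activity_kbq_ml), sum(vol), tolerance = 0.02)
  expect_true(min(rec$activity_kbq_ml) >= 0)
})

test_that("OSEM validates subsets and warns on empty data", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 24)
  y <- sinogram(geom, matrix(0, 24, geom$n_radial_bins), "counts")
  expect_error(osem(y, recon_params(subsets = 7), g), "divide")
  expect_warning(rec <- osem(y, recon_params(subsets = 8), g), "all-zero")
  expect_true(all(rec$activity_kbq_ml == 0))
})

test_that("reconstruction stays non-negative on noisy data", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 32)
  vol <- disc_volume(g, 33, 2)
  y <- simulate_acquisition(vol, g, geom = geom, count_scale = 0.05,
                            seed = 2, noise = TRUE)
  rec <- osem(y, recon_params(iterations = 2, subsets = 16), g)
  expect_gte(min(rec$activity_kbq_ml), 0)
})

test_that("log-likelihood is non-decreasing over full iterations", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 24)
  vol <- disc_volume(g, 30, 4) + disc_volume(g, 8, 12, center = c(-10, 5))
  muv <- mu_map(g, disc_volume(g, 30, 0.08))
  y <- simulate_acquisition(vol, g, mu = muv, geom = geom, count_scale = 0.4,
                            seed = 5, noise = TRUE)
  p <- recon_params(mu_map = muv, subsets = 4, psf_fwhm_mm = 0,
                    iterations = 1)
  ll <- numeric(6)
  for (k in seq_len(6)) {
    p$iterations <- k
    ll[k] <- recon_loglik(y, osem(y, p, g), p, g)
  }
  expect_true(all(diff(ll) > -1e-6))
})

test_that("zero-width PSF reduces exactly to the unmodelled pipeline", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 24)
  vol <- disc_volume(g, 25, 3)
  y <- simulate_acquisition(vol, g, geom = geom, seed = 4, noise = TRUE)
  a <- osem(y, recon_params(iterations = 2, subsets = 8, psf_fwhm_mm = 0), g)
  b <- osem(y, recon_params(iterations = 2, subsets = 8, psf_fwhm_mm = 0), g)
  expect_identical(a$activity_kbq_ml, b$activity_kbq_ml)
  ref <- reference_mlem(y, g, NULL, 2, y$scale)
  c2 <- osem(y, recon_params(iterations = 2, subsets = 1, psf_fwhm_mm = 0), g)
  expect_equal(c2$activity_kbq_ml, ref, tolerance = 1e-10)
})

test_that("sensitivity image is flat without attenuation and partitions", {
  g <- tiny_grid(32)
  geom <- tiny_geom(g, 32)
  p <- recon_params(subsets = 8, psf_fwhm_mm = 0)
  full <- sensitivity_image(p, geom, g, count_scale = 1)
  ax <- grid_axes(g)
  inside <- outer(ax[[1]]^2, ax[[2]]^2, `+`) <= (min(grid_fov_mm(g)) / 2 -
                                                 2 * g$voxel_size_mm[1])^2
  cv <- sd(full[inside]) / mean(full[inside])
  expect_lt(cv, 0.05)
  parts <- Reduce(`+`, lapply(1:8, function(s) {
    sensitivity_image(p, geom, g, subset = s, count_scale = 1)
  }))
  expect_equal(parts, full, tolerance = 1e-12)
  # larger mu, point-wise smaller sensitivity
  p2 <- recon_params(mu_map = mu_map(g, disc_volume(g, 40, 0.1)),
                     subsets = 8, psf_fwhm_mm = 0)
  expect_true(all(sensitivity_image(p2, geom, g, count_scale = 1) <=
                    full + 1e-12))
})

test_that("missing bone in the mu-map lowers recovered activity near bone", {
  ph <- small_phantom(64)
  g <- ph$grid
  geom <- default_geometry(g, 48)
  mu_ct <- hu_to_mu_ctac(ph$hu, g)
  mu_mr <- derive_mrac_dixon(ph$labels, g)
  sites <- default_target_sites(ph)
  les <- lesion_spec(sites$acetabulum$center_mm, 12, 5000)
  lam <- simulate_acquisition(ph$activity_kbq_ml + rasterize_lesion(les, g),
                              g, mu = mu_ct, geom = geom, noise = FALSE)
  rec_ct <- osem(lam, recon_params(mu_map = mu_ct), g)
  rec_mr <- osem(lam, recon_params(mu_map = mu_mr), g)
  m <- voi_mask(les$center_mm, 12, g)
  expect_lt(mean(rec_mr$activity_kbq_ml[m]), mean(rec_ct$activity_kbq_ml[m]))
})
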
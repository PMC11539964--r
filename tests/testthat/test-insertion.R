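test_that("lesion rasterization matches brute-force membership", {
  g <- tiny_grid(64)
  spec <- lesion_spec(c(10.5, -22), 12, 5000)
  vol <- rasterize_lesion(spec, g)
  m <- brute_force_mask(spec$center_mm, 12, g)
  expect_identical(vol > 0, m)
  expect_equal(max(vol), 5000)
  expect_equal(sort(unique(as.vector(vol))), c(0, 5000))
  # VOI masks share the same membership rule
  expect_identical(voi_mask(spec$center_mm, 12, g), m)
})

test_that("a sub-voxel lesion still fills its nearest voxel", {
  g <- tiny_grid(32)
  vol <- rasterize_lesion(lesion_spec(c(1.4, 1.4), 1, 100), g)
  expect_equal(sum(vol > 0), 1)
  expect_equal(max(vol), 100)
  expect_error(rasterize_lesion(lesion_spec(c(200, 0), 12, 100), g),
               "outside")
})

test_that("insertion adds the expected lesion counts to the base", {
  ph <- small_phantom(64)
  g <- ph$grid
  geom <- default_geometry(g, 48)
  mu <- hu_to_mu_ctac(ph$hu, g)
  base <- simulate_acquisition(ph$activity_kbq_ml, g, mu = mu, geom = geom,
                               seed = 1, noise = TRUE)
  expect_identical(insert_lesions(base, list(), g, mu = mu), base)
  les <- lesion_spec(c(-40, 10), 15, 40)
  hyb <- insert_lesions(base, list(les), g, mu = mu, seed = 2)
  lam_les <- simulate_acquisition(rasterize_lesion(les, g), g, mu = mu,
                                  geom = geom, count_scale = base$scale,
                                  noise = FALSE)
  added <- sum(hyb$values) - sum(base$values)
  expect_lt(abs(added - sum(lam_les$values)), 4 * sqrt(sum(lam_les$values)))
  # joint vs sequential insertion without noise is exactly linear
  base0 <- simulate_acquisition(ph$activity_kbq_ml, g, mu = mu, geom = geom,
                                noise = FALSE)
  l2 <- lesion_spec(c(35, -30), 10, 30)
  joint <- insert_lesions(base0, list(les, l2), g, mu = mu, noise = FALSE)
  seq1 <- insert_lesions(insert_lesions(base0, list(les), g, mu = mu,
                                        noise = FALSE),
                         list(l2), g, mu = mu, noise = FALSE)
  expect_equal(joint$values, seq1$values, tolerance = 1e-12)
})

test_that("matched study produces paired records with preserved diameters", {
  ph <- small_phantom(64)
  les <- sample_original_lesions(ph, 3, diameter_range_mm = c(9, 20),
                                 seed = 6)
  res <- run_matched_study(ph, les, geom = default_geometry(ph$grid, 48),
                           seed = 4, noise = TRUE)
  expect_equal(nrow(res$records), 3)
  expect_equal(res$records$diameter_mm,
               vapply(les, `[[`, numeric(1), "diameter_mm"))
  expect_true(all(res$records$suv_error_ratio_original > 0))
  expect_true(all(res$records$lesion_error_ratio > 0))
  expect_length(res$studies[[1]]$lesions, 6)  # originals + synthetics
  # midline lesions are rejected: the mirror twin would overlap
  bad <- lesion_spec(c(1, 0), 12, 25)
  expect_error(run_matched_study(ph, list(bad)), "midline")
})

test_that("matched insertion reproduces the original VOI in a noise-free
           symmetric phantom", {
  ph <- make_pelvis_phantom(tiny_grid(64), seed = 9, texture_sigma_hu = 0)
  les <- list(lesion_spec(c(-45, 25.5), 14, 30))
  # MLEM (one subset): the update has no subset-ordering asymmetry, so the
  # mirrored twin sees an exactly mirrored system
  res <- run_matched_study(ph, les, geom = default_geometry(ph$grid, 48),
                           params = recon_params(iterations = 4, subsets = 1),
                           noise = FALSE, contrast_from = "true")
  r <- res$records
  # symmetry oracle: identical surroundings, identical AC error
  expect_equal(r$suv_error_ratio_original, r$suv_error_ratio_synthetic,
               tolerance = 0.01)
  expect_equal(r$lesion_error_ratio, 1, tolerance = 0.01)
})

test_that("targeted study inserts 4 x 4 fixed lesions and flags collisions", {
  phantoms <- lapply(c(2, 3, 5, 8), function(s) small_phantom(64, seed = s))
  res <- run_targeted_study(phantoms, geom = default_geometry(tiny_grid(64),
                                                              48),
                            noise = FALSE, seed = 3)
  expect_equal(nrow(res$table), 16)
  expect_equal(sort(unique(res$table$site)),
               sort(c("acetabulum", "sacrum", "lymph_node",
                      "bladder_posterior")))
  expect_length(res$reports, 16)
  # every insertion used the fixed 12 mm / 5000 kBq/mL protocol
  for (st in res$studies) {
    expect_equal(st$lesions[[1]]$diameter_mm, 12)
    expect_equal(st$lesions[[1]]$activity_kbq_ml, 5000)
  }
  # a pre-existing lesion at a target site is rejected
  ph2 <- small_phantom(64)
  sites <- default_target_sites(ph2)
  ph2$activity_kbq_ml[voi_mask(sites$sacrum$center_mm, 8, ph2$grid)] <- 100
  expect_error(run_targeted_study(list(ph2), noise = FALSE), "pre-existing")
})
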
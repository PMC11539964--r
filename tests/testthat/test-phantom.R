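test_that("symmetric phantoms are exactly mirror-invariant for any seed", {
  g <- tiny_grid(64)
  for (seed in c(1, 7, 23)) {
    ph <- make_pelvis_phantom(g, seed = seed, symmetric = TRUE)
    expect_identical(ph$labels, mirror_lr(ph$labels))
    expect_identical(ph$activity_kbq_ml, mirror_lr(ph$activity_kbq_ml))
    expect_identical(ph$hu, mirror_lr(ph$hu))
  }
})

test_that("phantom construction is deterministic and conserves activity", {
  g <- tiny_grid(64)
  a <- make_pelvis_phantom(g, background_kbq_ml = 5, seed = 3)
  b <- make_pelvis_phantom(g, background_kbq_ml = 5, seed = 3)
  expect_identical(a$labels, b$labels)
  expect_identical(a$hu, b$hu)
  expect_identical(a$activity_kbq_ml, b$activity_kbq_ml)
  # total activity = background x non-air voxel count (per unit volume)
  n_tissue <- sum(a$labels != tissue_codes()[["air"]])
  expect_equal(sum(a$activity_kbq_ml), 5 * n_tissue)
  expect_true(all(a$activity_kbq_ml[a$labels == 0] == 0))
  # border is air
  expect_true(all(a$labels[c(1, 64), ] == 0))
  expect_true(all(a$labels[, c(1, 64)] == 0))
})

test_that("phantom rejects a grid too small for the body", {
  expect_error(make_pelvis_phantom(voxel_grid(c(8, 8), 3)), "too small")
})

test_that("labels_to_hu maps classes to nominal values and clips texture", {
  lab <- matrix(0L, 8, 8)
  expect_true(all(labels_to_hu(lab) == -1000))
  lab2 <- matrix(c(0L, 1L, 2L, 3L), 8, 8)
  hu0 <- labels_to_hu(lab2, texture_sigma_hu = 0)
  expect_setequal(unique(as.vector(hu0)), c(-1000, -90, 40, 700))
  hu1 <- labels_to_hu(lab2, seed = 5, texture_sigma_hu = 10)
  hu2 <- labels_to_hu(lab2, seed = 5, texture_sigma_hu = 10)
  expect_identical(hu1, hu2)
  expect_true(all(hu1[lab2 == 0L] <= -900))
  expect_true(all(hu1[lab2 == 3L] >= 200))
  expect_error(labels_to_hu(matrix(9L, 8, 8)), "tissue codes")
})

test_that("target sites exist, lie in the body, and order by bone fraction", {
  for (seed in c(2, 11)) {
    ph <- small_phantom(128, seed = seed)
    sites <- default_target_sites(ph)
    expect_length(sites, 4)
    bf <- vapply(sites, `[[`, numeric(1), "bone_fraction")
    expect_gt(bf[["acetabulum"]], 0.3)
    expect_gt(bf[["acetabulum"]], bf[["sacrum"]])
    expect_gt(bf[["sacrum"]], bf[["lymph_node"]])
    expect_gt(bf[["sacrum"]], bf[["bladder_posterior"]])
    expect_lt(bf[["lymph_node"]], 0.05)
    expect_lt(bf[["bladder_posterior"]], 0.05)
    for (s in sites) {
      # centre inside the body: its voxel is not air
      idx <- round(world_to_index(ph$grid, s$center_mm))
      expect_true(ph$labels[idx[1], idx[2]] != 0L)
      # reported fraction matches an independent brute-force count
      m <- brute_force_mask(s$center_mm, 12, ph$grid)
      expect_equal(s$bone_fraction, mean(ph$labels[m] == 3L))
    }
  }
})

test_that("site derivation fails without bone", {
  ph <- small_phantom(64)
  ph$labels[ph$labels == 3L] <- 2L
  expect_error(default_target_sites(ph), "no bone")
})
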
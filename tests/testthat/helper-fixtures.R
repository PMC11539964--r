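# Shared fixtures: everything is generated in code at test time.

tiny_grid <- function(n = 32, vox = 3) voxel_grid(c(n, n), vox)

tiny_geom <- function(grid, n_angles = 32) default_geometry(grid, n_angles)

# one small phantom per (n, seed), cached for the session
.fixture_env <- new.env()

small_phantom <- function(n = 64, seed = 2, ...) {
  key <- paste0("ph", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_pelvis_phantom(tiny_grid(n), seed = seed, ...)
  }
  .fixture_env[[key]]
}

# independent brute-force VOI membership oracle: explicit double loop over
# voxel centres, no shared code with voi_mask()
brute_force_mask <- function(center_mm, diameter_mm, grid) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  out <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      w <- grid$origin_mm + (c(i, j) - 1) * grid$voxel_size_mm
      if (sum((w - center_mm)^2) <= (diameter_mm / 2)^2) out[i, j] <- TRUE
    }
  }
  out
}

# uniform disc volume used by the projector oracles
disc_volume <- function(grid, radius_mm, value = 1, center = c(0, 0)) {
  ax <- grid_axes(grid)
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  vol <- array(0, grid$shape)
  vol[outer(dx2, dy2, `+`) <= radius_mm^2] <- value
  vol
}

# Independent reference MLEM: the classical update written directly from the
# EM equations with the package's projector primitives, no shared update code.
reference_mlem <- function(sino, grid, mu, iterations, count_scale) {
  geom <- sino$geometry
  att <- if (is.null(mu)) {
    matrix(1, geom$n_angles, geom$n_radial_bins)
  } else {
    attenuation_factors(mu, geom)$values
  }
  q <- count_scale * att
  ones <- sinogram(geom, q, "line_integral")
  sens <- back_project(ones, grid)
  x <- array(1, dim(sens))
  for (it in seq_len(iterations)) {
    fp <- q * forward_project(x, grid, geom)$values
    ratio <- ifelse(fp > 1e-12, sino$values / fp, 0)
    bp <- back_project(sinogram(geom, q * ratio, "line_integral"), grid)
    x <- x * ifelse(sens > 1e-12, bp / pmax(sens, 1e-12), 0)
  }
  x
}
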
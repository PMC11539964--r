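#' Parallel-beam system geometry
#'
#' Defines the projection-domain sampling: `n_angles` view angles uniformly
#' spaced over \[0, 180) degrees and `n_radial_bins` radial bins of width
#' `radial_spacing_mm`, centred on the grid centre. The radial extent must
#' cover the image diagonal of any grid it is used with.
#'
#' @param n_angles Number of view angles (>= 16). Default 96.
#' @param n_radial_bins Number of radial bins (odd recommended).
#' @param radial_spacing_mm Radial bin width, mm.
#' @return A `system_geometry` object with the fields above plus
#'   `angles_deg` and `fov_mm` (the radial field of view).
#' @seealso [default_geometry()] to derive a geometry from a grid.
#' @export
system_geometry <- function(n_angles = 96, n_radial_bins, radial_spacing_mm) {
  n_angles <- as.integer(n_angles)
  if (n_angles < 16L) stop("n_angles must be >= 16", call. = FALSE)
  n_radial_bins <- as.integer(n_radial_bins)
  if (n_radial_bins < 2L) stop("n_radial_bins must be >= 2", call. = FALSE)
  if (radial_spacing_mm <= 0) stop("radial_spacing_mm must be > 0",
                                   call. = FALSE)
  structure(
    list(n_angles = n_angles,
         angles_deg = (seq_len(n_angles) - 1) * 180 / n_angles,
         n_radial_bins = n_radial_bins,
         radial_spacing_mm = as.numeric(radial_spacing_mm),
         fov_mm = n_radial_bins * as.numeric(radial_spacing_mm)),
    class = "system_geometry"
  )
}

#' Derive a system geometry matched to a grid
#'
#' Radial spacing equals the in-plane voxel size and the (odd) number of
#' radial bins covers the image diagonal.
#'
#' @param grid A [voxel_grid()].
#' @param n_angles Number of view angles (default 96).
#' @return A [system_geometry()].
#' @export
default_geometry <- function(grid, n_angles = 96) {
  stopifnot_grid(grid)
  dr <- grid$voxel_size_mm[1]
  half_diag <- sqrt(sum(((grid$shape[1:2] - 1) / 2 * grid$voxel_size_mm[1:2])^2))
  n_r <- 2L * as.integer(ceiling(half_diag / dr)) + 3L
  system_geometry(n_angles = n_angles, n_radial_bins = n_r,
                  radial_spacing_mm = dr)
}

#' @export
print.system_geometry <- function(x, ...) {
  cat(sprintf("<system_geometry> %d angles x %d radial bins @ %.3g mm\n",
              x$n_angles, x$n_radial_bins, x$radial_spacing_mm))
  invisible(x)
}

geom_key <- function(geom) {
  paste(geom$n_angles, geom$n_radial_bins,
        signif(geom$radial_spacing_mm, 12), sep = "|")
}

same_geometry <- function(a, b) identical(geom_key(a), geom_key(b))

#' Construct a sinogram
#'
#' A sinogram holds one value per (angle, radial bin) pair together with its
#' geometry and a `kind` tag: `"line_integral"` (units value x mm),
#' `"factors"` (dimensionless attenuation factors), `"expected_counts"` or
#' `"counts"` (integer-valued Poisson data).
#'
#' @param geometry A [system_geometry()].
#' @param values Numeric matrix `n_angles x n_radial_bins`.
#' @param kind One of `"line_integral"`, `"factors"`, `"expected_counts"`,
#'   `"counts"`.
#' @param scale Counts per (kBq/mL x mm) used when `kind` involves counts.
#' @return A `sinogram` object.
#' @export
sinogram <- function(geometry, values, kind, scale = 1) {
  if (!inherits(geometry, "system_geometry")) {
    stop("`geometry` must be a system_geometry", call. = FALSE)
  }
  kind <- match.arg(kind,
                    c("line_integral", "factors", "expected_counts", "counts"))
  values <- as.matrix(values)
  if (!identical(dim(values), c(geometry$n_angles, geometry$n_radial_bins))) {
    stop("sinogram shape does not match geometry", call. = FALSE)
  }
  if (kind == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      stop("counts sinogram must be non-negative and integer-valued",
           call. = FALSE)
    }
  }
  if (kind == "expected_counts" && any(values < 0)) {
    stop("expected counts must be non-negative", call. = FALSE)
  }
  structure(list(geometry = geometry, values = values, kind = kind,
                 scale = as.numeric(scale)),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %s; %d x %d; total %.6g\n", x$kind,
              x$geometry$n_angles, x$geometry$n_radial_bins, sum(x$values)))
  invisible(x)
}

#' Detector normalization map
#'
#' Per-bin detection efficiencies in (0, 2]; the default is an ideal
#' (all-ones) system.
#'
#' @param geometry A [system_geometry()].
#' @param efficiency Scalar or `n_angles x n_radial_bins` matrix.
#' @return A `normalization_map`.
#' @export
normalization_map <- function(geometry, efficiency = 1) {
  if (length(efficiency) == 1) {
    efficiency <- matrix(efficiency, geometry$n_angles,
                         geometry$n_radial_bins)
  }
  efficiency <- as.matrix(efficiency)
  if (!identical(dim(efficiency),
                 c(geometry$n_angles, geometry$n_radial_bins))) {
    stop("efficiency shape does not match geometry", call. = FALSE)
  }
  if (any(efficiency <= 0) || any(efficiency > 2)) {
    stop("efficiencies must lie in (0, 2]", call. = FALSE)
  }
  structure(list(geometry = geometry, efficiency = efficiency),
            class = "normalization_map")
}

# --- sparse projector -------------------------------------------------------

.projector_cache <- new.env(parent = emptyenv())

# Pixel-driven linear-interpolation projector: each voxel centre projects to
# the radial coordinate r = (x - cx) cos(theta) + (y - cy) sin(theta) about
# the grid centre and deposits (voxel area / bin width) into the two
# neighbouring bins. Interpolation weights sum to one per voxel, so every
# angle conserves total mass exactly: sum_k p(theta, r_k) * dr =
# sum_i v_i * voxel_area.
projector_matrix <- function(grid, geom) {
  if (length(grid$shape) != 2L) {
    stop("the projector operates on single axial slices (2-D grids)",
         call. = FALSE)
  }
  key <- paste(grid_key(grid), geom_key(geom), sep = "#")
  hit <- .projector_cache[[key]]
  if (!is.null(hit)) return(hit)
  nx <- grid$shape[1]; ny <- grid$shape[2]
  axes <- grid_axes(grid)
  cx <- grid$origin_mm[1] + (nx - 1) / 2 * grid$voxel_size_mm[1]
  cy <- grid$origin_mm[2] + (ny - 1) / 2 * grid$voxel_size_mm[2]
  x <- rep(axes[[1]] - cx, times = ny)
  y <- rep(axes[[2]] - cy, each = nx)
  dr <- geom$radial_spacing_mm
  n_r <- geom$n_radial_bins
  half_diag <- sqrt(max(x^2) + max(y^2))
  if ((n_r - 1) / 2 * dr < half_diag) {
    stop("geometry/grid mismatch: radial extent does not cover the image ",
         "diagonal", call. = FALSE)
  }
  w_int <- grid$voxel_size_mm[1] * grid$voxel_size_mm[2] / dr
  nvox <- nx * ny
  th <- geom$angles_deg * pi / 180
  ii <- jj <- xx <- vector("list", geom$n_angles)
  for (a in seq_len(geom$n_angles)) {
    r <- x * cos(th[a]) + y * sin(th[a])
    t <- r / dr + (n_r + 1) / 2          # fractional (1-based) bin index
    k0 <- floor(t)
    f <- t - k0
    rows0 <- (a - 1L) * n_r + k0
    ok0 <- k0 >= 1 & k0 <= n_r
    ok1 <- k0 + 1 >= 1 & k0 + 1 <= n_r
    ii[[a]] <- c(rows0[ok0], rows0[ok1] + 1L)
    jj[[a]] <- c(which(ok0), which(ok1))
    xx[[a]] <- c((1 - f)[ok0], f[ok1]) * w_int
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(geom$n_angles * n_r, nvox))
  A <- methods::as(A, "CsparseMatrix")
  .projector_cache[[key]] <- list(A = A, At = Matrix::t(A))
  .projector_cache[[key]]
}

sino_from_vec <- function(v, geom) {
  matrix(v, nrow = geom$n_angles, ncol = geom$n_radial_bins, byrow = TRUE)
}

vec_from_sino <- function(values) as.vector(t(values))

#' Forward-project a volume into a sinogram
#'
#' Discrete Radon transform under the parallel-beam geometry: each bin holds
#' the line integral of the volume along its line of response, in units of
#' (volume value) x mm. The operator is linear and mass-conserving per angle.
#'
#' @param volume Numeric array on `grid` (finite).
#' @param grid A [voxel_grid()].
#' @param geom A [system_geometry()] whose radial extent covers the grid
#'   diagonal.
#' @return A [sinogram()] of kind `"line_integral"`.
#' @export
forward_project <- function(volume, grid, geom) {
  stopifnot_grid(grid)
  if (any(!is.finite(volume))) stop("volume must be finite", call. = FALSE)
  if (!identical(dim(volume), dim_of(grid))) {
    stop("geometry/grid mismatch: volume shape does not match grid",
         call. = FALSE)
  }
  P <- projector_matrix(grid, geom)
  v <- as.numeric(P$A %*% as.vector(volume))
  sinogram(geom, sino_from_vec(v, geom), "line_integral")
}

#' Back-project a sinogram (adjoint of the forward projector)
#'
#' The exact matrix transpose of [forward_project()]; used by the OSEM update
#' and sensitivity computation.
#'
#' @param sino A [sinogram()].
#' @param grid A [voxel_grid()].
#' @return Numeric array on `grid`.
#' @export
back_project <- function(sino, grid) {
  stopifnot_grid(grid)
  P <- projector_matrix(grid, sino$geometry)
  array(as.numeric(P$At %*% vec_from_sino(sino$values)), dim = dim_of(grid))
}

#' Attenuation factors for a mu-map
#'
#' Per-bin survival probability of a 511 keV photon pair along each line of
#' response: `a = exp(-integral of mu dl)`, with the line integral computed
#' by [forward_project()] on the mu-map (1/cm converted to 1/mm). All factors
#' lie in (0, 1]; mu identically zero gives factors identically one.
#'
#' @param mu A `mu_map` (see [mu_map()]).
#' @param geom A [system_geometry()].
#' @return A [sinogram()] of kind `"factors"`.
#' @export
attenuation_factors <- function(mu, geom) {
  if (!inherits(mu, "mu_map")) stop("`mu` must be a mu_map", call. = FALSE)
  if (any(mu$mu_per_cm < 0)) stop("mu must be non-negative", call. = FALSE)
  li <- forward_project(mu$mu_per_cm, mu$grid, geom)   # (1/cm) x mm
  sinogram(geom, exp(-li$values / 10), "factors")
}

#' Simulate a PET acquisition
#'
#' Expected counts per bin are
#' `lambda = count_scale * norm * attenuation_factors(mu) * forward_project(activity)`;
#' with `noise = TRUE` one Poisson draw per bin is returned (reproducible for
#' a fixed seed), otherwise the expectation itself.
#'
#' @param activity Activity volume (kBq/mL) on `grid`.
#' @param grid A [voxel_grid()].
#' @param mu A `mu_map`, or `NULL` for no attenuation.
#' @param norm A [normalization_map()], or `NULL` for an ideal system.
#' @param geom A [system_geometry()].
#' @param count_scale Counts per (kBq/mL x mm) of line integral (> 0);
#'   default [default_count_scale()].
#' @param seed Integer seed for the Poisson draw.
#' @param noise Draw Poisson counts (default `TRUE`).
#' @return A [sinogram()] of kind `"counts"` or `"expected_counts"`, with
#'   `scale = count_scale`.
#' @export
simulate_acquisition <- function(activity, grid, mu = NULL, norm = NULL,
                                 geom, count_scale = default_count_scale(),
                                 seed = 1, noise = TRUE) {
  if (count_scale <= 0) stop("count_scale must be > 0", call. = FALSE)
  lam <- count_scale * forward_project(activity, grid, geom)$values
  if (!is.null(mu)) lam <- lam * attenuation_factors(mu, geom)$values
  if (!is.null(norm)) {
    if (!same_geometry(norm$geometry, geom)) {
      stop("normalization geometry mismatch", call. = FALSE)
    }
    lam <- lam * norm$efficiency
  }
  if (isTRUE(noise)) {
    set.seed(as.integer(seed))
    y <- matrix(stats::rpois(length(lam), lambda = as.vector(lam)),
                nrow = nrow(lam))
    sinogram(geom, y, "counts", scale = count_scale)
  } else {
    sinogram(geom, lam, "expected_counts", scale = count_scale)
  }
}

#' Add two sinograms element-wise
#'
#' Both operands must share the same geometry and kind; the kind (and count
#' scale) is preserved.
#'
#' @param a,b [sinogram()] objects.
#' @return A [sinogram()].
#' @export
add_sinograms <- function(a, b) {
  if (!inherits(a, "sinogram") || !inherits(b, "sinogram")) {
    stop("operands must be sinograms", call. = FALSE)
  }
  if (!same_geometry(a$geometry, b$geometry)) {
    stop("sinogram geometry mismatch", call. = FALSE)
  }
  if (!identical(a$kind, b$kind)) {
    stop("sinogram kind mismatch: ", a$kind, " vs ", b$kind, call. = FALSE)
  }
  sinogram(a$geometry, a$values + b$values, a$kind, scale = a$scale)
}

#' Default count scale
#'
#' Counts recorded per (kBq/mL x mm) of attenuated line integral. The default
#' is set so the reference pelvis phantom (128 x 128 voxels at 3 mm, 5 kBq/mL
#' background, 96 angles) yields about 5e5 true counts per slice.
#'
#' @return Scalar count scale.
#' @export
default_count_scale <- function() 0.46
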
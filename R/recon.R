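#' Reconstruction parameters
#'
#' Bundles the OSEM settings and the system-model components used during
#' reconstruction: the attenuation map hypothesis, detector normalization,
#' image-space PSF width and the count scale. Defaults follow the clinical
#' protocol modelled here: 2 iterations, 16 subsets, 4.5 mm FWHM PSF.
#'
#' @param mu_map A `mu_map` used inside the reconstruction system model
#'   (`NULL` for no attenuation correction).
#' @param iterations Full OSEM iterations (>= 1). Default 2.
#' @param subsets Number of angular subsets (>= 1; must divide the number of
#'   view angles). Default 16.
#' @param psf_fwhm_mm Isotropic Gaussian PSF full width at half maximum, mm
#'   (0 disables resolution modelling). Default 4.5.
#' @param norm A [normalization_map()] or `NULL` (ideal system).
#' @param count_scale Counts per (kBq/mL x mm), or `NULL` to take the scale
#'   recorded on the sinogram being reconstructed.
#' @return A `recon_params` object.
#' @export
recon_params <- function(mu_map = NULL, iterations = 2, subsets = 16,
                         psf_fwhm_mm = 4.5, norm = NULL, count_scale = NULL) {
  iterations <- as.integer(iterations)
  subsets <- as.integer(subsets)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (subsets < 1L) stop("subsets must be >= 1", call. = FALSE)
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0", call. = FALSE)
  structure(list(mu_map = mu_map, iterations = iterations, subsets = subsets,
                 psf_fwhm_mm = as.numeric(psf_fwhm_mm), norm = norm,
                 count_scale = count_scale),
            class = "recon_params")
}

# --- image-space PSF --------------------------------------------------------

# Separable Gaussian convolution with zero padding. The kernel is symmetric,
# so the operator is exactly self-adjoint — required for a matched OSEM
# forward/backward pair.
gaussian_kernel_1d <- function(sigma_vox) {
  radius <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-0.5 * ((-radius:radius) / sigma_vox)^2)
  k / sum(k)
}

convolve_axis <- function(img, kernel, axis) {
  radius <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = dim(img))
  n <- dim(img)[axis]
  for (o in -radius:radius) {
    w <- kernel[o + radius + 1L]
    src <- seq_len(n) + o
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    if (axis == 1L) {
      out[which(keep), ] <- out[which(keep), ] + w * img[src[keep], ]
    } else {
      out[, which(keep)] <- out[, which(keep)] + w * img[, src[keep]]
    }
  }
  out
}

psf_blur <- function(img, fwhm_mm, grid) {
  if (fwhm_mm <= 0) return(img)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  kx <- gaussian_kernel_1d(sigma_mm / grid$voxel_size_mm[1])
  ky <- gaussian_kernel_1d(sigma_mm / grid$voxel_size_mm[2])
  convolve_axis(convolve_axis(img, kx, 1L), ky, 2L)
}

# --- OSEM -------------------------------------------------------------------

osem_subset_rows <- function(geom, subsets) {
  lapply(seq_len(subsets), function(s) {
    angles <- which(((seq_len(geom$n_angles) - 1L) %% subsets) + 1L == s)
    as.vector(vapply(angles, function(a) {
      (a - 1L) * geom$n_radial_bins + seq_len(geom$n_radial_bins)
    }, integer(geom$n_radial_bins)))
  })
}

osem_model <- function(params, geom, grid, scale) {
  P <- projector_matrix(grid, geom)
  q <- rep(scale, geom$n_angles * geom$n_radial_bins)
  if (!is.null(params$mu_map)) {
    if (!same_grid(params$mu_map$grid, grid)) {
      stop("mu-map grid does not match reconstruction grid", call. = FALSE)
    }
    q <- q * vec_from_sino(attenuation_factors(params$mu_map, geom)$values)
  }
  if (!is.null(params$norm)) {
    if (!same_geometry(params$norm$geometry, geom)) {
      stop("normalization geometry mismatch", call. = FALSE)
    }
    q <- q * vec_from_sino(params$norm$efficiency)
  }
  rows <- osem_subset_rows(geom, params$subsets)
  list(P = P, q = q, rows = rows)
}

#' OSEM reconstruction
#'
#' Ordered-subsets expectation maximization with the attenuation factors,
#' normalization, count scale and image-space PSF inside the system model and
#' its matched adjoint. Angles are assigned to subsets round-robin and
#' processed in fixed order; the initial image is uniform. The multiplicative
#' EM update preserves non-negativity; with one subset the update is the
#' classical MLEM iteration.
#'
#' @param sino A [sinogram()] of kind `"counts"` (or `"expected_counts"` for
#'   noiseless studies).
#' @param params A [recon_params()]; `params$subsets` must divide the number
#'   of view angles.
#' @param grid Reconstruction [voxel_grid()].
#' @return A `recon_image`: list with `grid`, `activity_kbq_ml` (non-negative
#'   array, kBq/mL), `params` and `provenance`.
#' @export
osem <- function(sino, params, grid) {
  if (!inherits(sino, "sinogram")) stop("`sino` must be a sinogram",
                                        call. = FALSE)
  if (!sino$kind %in% c("counts", "expected_counts")) {
    stop("sinogram must carry counts or expected counts", call. = FALSE)
  }
  if (!inherits(params, "recon_params")) {
    stop("`params` must be recon_params", call. = FALSE)
  }
  geom <- sino$geometry
  if (geom$n_angles %% params$subsets != 0L) {
    stop("subsets (", params$subsets, ") must divide n_angles (",
         geom$n_angles, ")", call. = FALSE)
  }
  scale <- if (is.null(params$count_scale)) sino$scale else params$count_scale
  if (sum(sino$values) == 0) {
    warning("all-zero sinogram; returning zero image")
    return(new_recon_image(array(0, dim_of(grid)), grid, params, sino))
  }
  m <- osem_model(params, geom, grid, scale)
  y <- vec_from_sino(sino$values)
  fwhm <- params$psf_fwhm_mm
  eps <- 1e-12
  sub <- lapply(seq_len(params$subsets), function(s) {
    r <- m$rows[[s]]
    As <- m$P$A[r, , drop = FALSE]
    tAs <- Matrix::t(As)
    qs <- m$q[r]
    list(As = As, tAs = tAs, qs = qs, y = y[r],
         sens = psf_blur(array(as.numeric(tAs %*% qs), dim_of(grid)),
                         fwhm, grid))
  })
  x <- array(1, dim = dim_of(grid))
  for (it in seq_len(params$iterations)) {
    for (s in sub) {
      fp <- s$qs * as.numeric(s$As %*% as.vector(psf_blur(x, fwhm, grid)))
      ratio <- ifelse(fp > eps, s$y / fp, 0)
      bp <- psf_blur(array(as.numeric(s$tAs %*% (s$qs * ratio)),
                           dim_of(grid)), fwhm, grid)
      upd <- ifelse(s$sens > eps, bp / pmax(s$sens, eps), 0)
      x <- x * array(upd, dim_of(grid))
    }
  }
  new_recon_image(x, grid, params, sino)
}

new_recon_image <- function(x, grid, params, sino) {
  structure(
    list(grid = grid, activity_kbq_ml = x, params = params,
         provenance = list(
           mu_method = if (is.null(params$mu_map)) "none"
                       else params$mu_map$method,
           iterations = params$iterations, subsets = params$subsets,
           psf_fwhm_mm = params$psf_fwhm_mm,
           sinogram_kind = sino$kind, count_scale = sino$scale)),
    class = "recon_image"
  )
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf(
    "<recon_image> %s AC; %d it x %d subsets; max %.3g kBq/mL\n",
    x$provenance$mu_method, x$params$iterations, x$params$subsets,
    max(x$activity_kbq_ml)))
  invisible(x)
}

#' Subset sensitivity image
#'
#' Back-projection of an all-ones sinogram (restricted to one angular subset,
#' or the full angle set) through the same system model as [osem()]:
#' attenuation, normalization, count scale and PSF adjoint. Subset
#' sensitivities sum to the full sensitivity by partition of angles.
#'
#' @param params A [recon_params()].
#' @param geom A [system_geometry()].
#' @param grid A [voxel_grid()].
#' @param subset Subset index in `1..params$subsets`, or `NULL` for all
#'   angles.
#' @param count_scale Counts per (kBq/mL x mm); default
#'   [default_count_scale()].
#' @return Numeric array on `grid`.
#' @export
sensitivity_image <- function(params, geom, grid, subset = NULL,
                              count_scale = default_count_scale()) {
  m <- osem_model(params, geom, grid, count_scale)
  r <- if (is.null(subset)) {
    seq_len(geom$n_angles * geom$n_radial_bins)
  } else {
    if (subset < 1L || subset > params$subsets) {
      stop("invalid subset index", call. = FALSE)
    }
    m$rows[[subset]]
  }
  psf_blur(array(as.numeric(Matrix::t(m$P$A[r, , drop = FALSE]) %*% m$q[r]),
                 dim_of(grid)),
           params$psf_fwhm_mm, grid)
}

#' Poisson log-likelihood of an image given a counts sinogram
#'
#' Computes `sum(y * log(lambda) - lambda)` (dropping the `log(y!)` constant)
#' with `lambda` the full system-model forward projection of the image. Used
#' to verify the EM monotonicity property.
#'
#' @param sino A counts [sinogram()].
#' @param image A `recon_image` or plain activity array.
#' @param params A [recon_params()].
#' @param grid A [voxel_grid()].
#' @return Scalar log-likelihood.
#' @export
recon_loglik <- function(sino, image, params, grid) {
  x <- if (inherits(image, "recon_image")) image$activity_kbq_ml else image
  scale <- if (is.null(params$count_scale)) sino$scale else params$count_scale
  m <- osem_model(params, sino$geometry, grid, scale)
  lam <- m$q * as.numeric(m$P$A %*% as.vector(
    psf_blur(x, params$psf_fwhm_mm, grid)))
  y <- vec_from_sino(sino$values)
  keep <- lam > 0
  sum(y[keep] * log(lam[keep]) - lam[keep]) - sum(lam[!keep])
}
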
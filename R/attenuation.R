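#' Convert CT numbers to 511 keV linear attenuation coefficients (CTAC)
#'
#' Standard bilinear scaling of Hounsfield units to linear attenuation at
#' 511 keV: for `HU <= 0`, `mu = mu_water * (1 + HU/1000)`; for `HU > 0`,
#' `mu = mu_water + HU * slope_bone`. Negative results (HU below -1000) are
#' clamped to zero. The map is monotone non-decreasing in HU.
#'
#' @param hu Numeric array of Hounsfield units (finite).
#' @param grid A [voxel_grid()] the volume lives on.
#' @param mu_water Water attenuation at 511 keV, 1/cm. Default 0.0975.
#' @param slope_bone Slope of the bone limb, 1/cm per HU. Default 5.64e-5.
#' @return A `mu_map`: list with `grid`, `mu_per_cm` and `method = "CTAC"`.
#' @examples
#' g <- voxel_grid(c(8, 8), 3)
#' m <- hu_to_mu_ctac(array(0, c(8, 8)), g)
#' m$mu_per_cm[1, 1]  # 0.0975, the water point
#' @export
hu_to_mu_ctac <- function(hu, grid, mu_water = 0.0975, slope_bone = 5.64e-5) {
  stopifnot_grid(grid)
  if (any(!is.finite(hu))) stop("HU volume must be finite", call. = FALSE)
  if (!identical(dim(hu), dim_of(grid))) {
    stop("HU volume shape does not match grid", call. = FALSE)
  }
  mu <- ifelse(hu <= 0, mu_water * (1 + hu / 1000), mu_water + hu * slope_bone)
  mu <- array(pmax(mu, 0), dim = dim(hu))
  new_mu_map(grid, mu, "CTAC")
}

#' Dixon-style segmentation coefficients
#'
#' The fixed per-class attenuation coefficients assigned by the simulated
#' Dixon water/fat segmentation. By default they are calibrated to the CTAC
#' bilinear map evaluated at the nominal class CT numbers, with bone assigned
#' the soft-tissue coefficient — the defining "bone-free" property of
#' segmentation-based MR attenuation correction. Calibrating fat and soft
#' tissue to their CT-derived values models a segmentation that is accurate
#' for the tissues it can see; the AC error under study is then attributable
#' to the missing bone alone. Any fixed coefficients (e.g. the conventional
#' water 0.0975 / fat 0.086 pair) can be supplied instead.
#'
#' @param hu_values Named nominal HU per class, default [nominal_hu()].
#' @param mu_water,slope_bone CTAC bilinear parameters, as in
#'   [hu_to_mu_ctac()].
#' @return Named numeric vector of 1/cm coefficients for air, fat, soft and
#'   bone (bone equal to soft).
#' @export
dixon_coefficients <- function(hu_values = nominal_hu(), mu_water = 0.0975,
                               slope_bone = 5.64e-5) {
  bilinear <- function(h) {
    max(0, if (h <= 0) mu_water * (1 + h / 1000) else mu_water + h * slope_bone)
  }
  soft <- bilinear(hu_values[["soft"]])
  c(air = 0, fat = bilinear(hu_values[["fat"]]), soft = soft, bone = soft)
}

#' Derive a bone-free Dixon-style attenuation map (MRAC)
#'
#' Assigns one fixed 511 keV coefficient per tissue class from a perfect
#' water/fat segmentation of the label volume; bone receives the soft-tissue
#' coefficient, reproducing the bone-free attenuation map of segmentation
#' MRAC. The segmentation itself is taken from the ground-truth labels: the
#' method under study is the consequence of the missing bone, not Dixon
#' segmentation fidelity.
#'
#' @param labels Integer tissue label array ([tissue_codes()]).
#' @param grid A [voxel_grid()].
#' @param coefficients Named 1/cm coefficients for air/fat/soft/bone; default
#'   [dixon_coefficients()].
#' @return A `mu_map` with `method = "MRAC_dixon"`.
#' @export
derive_mrac_dixon <- function(labels, grid,
                              coefficients = dixon_coefficients()) {
  stopifnot_grid(grid)
  codes <- tissue_codes()
  if (!all(labels %in% codes)) {
    stop("unknown tissue label code", call. = FALSE)
  }
  if (!all(names(codes) %in% names(coefficients))) {
    stop("`coefficients` must name air, fat, soft and bone", call. = FALSE)
  }
  mu <- array(coefficients[match(as.vector(labels), codes)],
              dim = dim(labels))
  new_mu_map(grid, mu, "MRAC_dixon")
}

#' Construct an attenuation map from raw coefficients
#'
#' @param grid A [voxel_grid()].
#' @param mu_per_cm Non-negative array of 1/cm values at 511 keV.
#' @param method One of `"CTAC"`, `"MRAC_dixon"`, `"custom"`.
#' @return A `mu_map` object.
#' @export
mu_map <- function(grid, mu_per_cm, method = "custom") {
  new_mu_map(grid, mu_per_cm, method)
}

new_mu_map <- function(grid, mu, method) {
  stopifnot_grid(grid)
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("mu must be finite and non-negative", call. = FALSE)
  }
  if (!identical(dim(mu), dim_of(grid))) {
    stop("mu volume shape does not match grid", call. = FALSE)
  }
  method <- match.arg(method, c("CTAC", "MRAC_dixon", "custom"))
  structure(list(grid = grid, mu_per_cm = mu, method = method),
            class = "mu_map")
}

#' @export
print.mu_map <- function(x, ...) {
  cat(sprintf("<mu_map> %s; mu in [%.4f, %.4f] 1/cm\n", x$method,
              min(x$mu_per_cm), max(x$mu_per_cm)))
  invisible(x)
}

dim_of <- function(grid) as.integer(grid$shape)
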
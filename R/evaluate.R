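#' Scan metadata for SUV normalization
#'
#' @param injected_dose_mbq Injected dose, MBq (decay-corrected to scan
#'   start), strictly positive.
#' @param patient_weight_kg Patient body weight, kg, strictly positive.
#' @return A `scan_meta` object.
#' @export
scan_meta <- function(injected_dose_mbq = 370, patient_weight_kg = 70) {
  if (!is.finite(injected_dose_mbq) || injected_dose_mbq <= 0) {
    stop("injected dose must be > 0", call. = FALSE)
  }
  if (!is.finite(patient_weight_kg) || patient_weight_kg <= 0) {
    stop("patient weight must be > 0", call. = FALSE)
  }
  structure(list(injected_dose_mbq = as.numeric(injected_dose_mbq),
                 patient_weight_kg = as.numeric(patient_weight_kg)),
            class = "scan_meta")
}

#' Convert activity concentration to standardized uptake values
#'
#' `SUV = activity (kBq/mL) / (injected dose (kBq) / body weight (g))`, with
#' 1 MBq = 1000 kBq and weight in g = 1000 x kg. The map is linear and the
#' output unitless; a uniform distribution of the whole dose in the body
#' would read SUV 1.
#'
#' @param activity_kbq_ml Activity array, kBq/mL.
#' @param meta A [scan_meta()].
#' @return Unitless SUV array of the same shape.
#' @examples
#' to_suv(5, scan_meta(370, 74))  # == 1
#' @export
to_suv <- function(activity_kbq_ml, meta) {
  if (!inherits(meta, "scan_meta")) stop("`meta` must be scan_meta",
                                         call. = FALSE)
  activity_kbq_ml /
    (meta$injected_dose_mbq * 1000 / (meta$patient_weight_kg * 1000))
}

#' Spherical (circular in 2-D) VOI mask
#'
#' A voxel belongs to the VOI iff its centre lies within `diameter_mm / 2` of
#' `center_mm` — the same membership rule used to rasterize lesions, so a
#' lesion and its VOI share identical support.
#'
#' @param center_mm World coordinates of the VOI centre (mm).
#' @param diameter_mm VOI diameter (mm), > 0.
#' @param grid A [voxel_grid()].
#' @return Logical array on `grid`.
#' @export
voi_mask <- function(center_mm, diameter_mm, grid) {
  stopifnot_grid(grid)
  if (diameter_mm <= 0) stop("diameter must be > 0", call. = FALSE)
  axes <- grid_axes(grid)
  r2 <- (diameter_mm / 2)^2
  if (length(grid$shape) == 2L) {
    dx2 <- (axes[[1]] - center_mm[1])^2
    dy2 <- (axes[[2]] - center_mm[2])^2
    mask <- outer(dx2, dy2, `+`) <= r2
  } else {
    dx2 <- (axes[[1]] - center_mm[1])^2
    dy2 <- (axes[[2]] - center_mm[2])^2
    dz2 <- (axes[[3]] - center_mm[3])^2
    mask <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
  }
  lo <- center_mm - diameter_mm / 2
  hi <- center_mm + diameter_mm / 2
  bounds <- index_to_world(grid, matrix(1, 1, length(grid$shape)))
  top <- index_to_world(grid, matrix(grid$shape, 1))
  half <- grid$voxel_size_mm / 2
  if (any(lo < bounds - half) || any(hi > top + half)) {
    stop("VOI extends outside the grid", call. = FALSE)
  }
  if (!any(mask)) stop("degenerate VOI: no voxel centres captured",
                       call. = FALSE)
  mask
}

#' VOI summary statistics
#'
#' @param suv SUV (or activity) array.
#' @param mask Logical VOI mask.
#' @param labels Optional tissue label array for the bone fraction.
#' @return A list with `mean_suv`, `max_suv`, `n_voxels` and (if labels are
#'   given) `bone_fraction`.
#' @export
voi_stats <- function(suv, mask, labels = NULL) {
  if (!any(mask)) stop("empty VOI mask", call. = FALSE)
  vals <- suv[mask]
  out <- list(mean_suv = mean(vals), max_suv = max(vals),
              n_voxels = sum(mask))
  if (!is.null(labels)) out$bone_fraction <- voi_bone_fraction(mask, labels)
  out
}

#' SUV Error Ratio
#'
#' Ratio of VOI mean SUVs under the two attenuation corrections,
#' `mean(SUV_MRAC) / mean(SUV_CTAC)`; unity means the AC choice does not
#' affect the VOI quantitation.
#'
#' @param mean_mrac,mean_ctac VOI mean SUVs; `mean_ctac` must be > 0.
#' @return Scalar ratio.
#' @export
suv_error_ratio <- function(mean_mrac, mean_ctac) {
  if (!is.finite(mean_ctac) || mean_ctac <= 0) {
    stop("degenerate VOI: CTAC mean must be > 0", call. = FALSE)
  }
  mean_mrac / mean_ctac
}

#' Lesion Error Ratio
#'
#' Ratio of the original lesion's SUV Error Ratio to its matched contralateral
#' synthetic lesion's SUV Error Ratio. Unity indicates the synthetic lesion
#' reproduces the original's AC-error behaviour.
#'
#' @param original_ratio,synthetic_ratio SUV Error Ratios;
#'   `synthetic_ratio` must be > 0.
#' @return Scalar ratio.
#' @export
lesion_error_ratio <- function(original_ratio, synthetic_ratio) {
  if (!is.finite(synthetic_ratio) || synthetic_ratio <= 0) {
    stop("degenerate synthetic SUV Error Ratio", call. = FALSE)
  }
  original_ratio / synthetic_ratio
}

#' Voxel-wise SUV difference percentages
#'
#' For every masked voxel, `100 * (SUV_MRAC - SUV_CTAC) / SUV_CTAC`. Voxels
#' whose CTAC SUV falls below `floor` are excluded from the result and
#' counted in the `n_excluded` attribute.
#'
#' @param suv_mrac,suv_ctac Co-registered SUV arrays.
#' @param mask Logical VOI mask (non-empty).
#' @param floor Exclusion threshold on `SUV_CTAC` (default 1e-6).
#' @return Numeric vector of percentages with attribute `n_excluded`.
#' @export
voxel_diff_percent <- function(suv_mrac, suv_ctac, mask, floor = 1e-6) {
  if (!any(mask)) stop("empty VOI mask", call. = FALSE)
  a <- suv_mrac[mask]
  b <- suv_ctac[mask]
  keep <- b >= floor
  if (!any(keep)) stop("degenerate VOI: all CTAC voxels below floor",
                       call. = FALSE)
  structure(100 * (a[keep] - b[keep]) / b[keep],
            n_excluded = sum(!keep))
}

#' RMSE from first two moments
#'
#' `RMSE = sqrt(mu^2 + sigma^2)`: the root-mean-squared error of a set of
#' differences decomposes exactly into its mean (bias) and standard
#' deviation (population form) components.
#'
#' @param mu Mean difference.
#' @param sigma Population standard deviation of the differences.
#' @return Scalar RMSE.
#' @examples
#' rmse_from_moments(-10.91, 4.23)  # 11.70 to 2 dp
#' @export
rmse_from_moments <- function(mu, sigma) sqrt(mu^2 + sigma^2)

#' Summarise voxel-wise difference percentages
#'
#' Mean, standard deviation (population divisor `N` — the VOI voxel
#' population is exhaustive, not sampled), `RMSE = sqrt(mu^2 + sigma^2)`, the
#' maximum absolute difference, and the signed largest-magnitude difference
#' (`diff_max_pct`).
#'
#' @param diffs Non-empty numeric vector of difference percentages (as from
#'   [voxel_diff_percent()]).
#' @return A `diff_report` list: `mu_pct`, `sigma_pct`, `rmse_pct`,
#'   `max_abs_pct`, `diff_max_pct`, `n_voxels`.
#' @export
diff_stats <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) == 0) stop("empty difference list", call. = FALSE)
  mu <- mean(diffs)
  sigma <- sqrt(mean((diffs - mu)^2))
  structure(
    list(mu_pct = mu, sigma_pct = sigma,
         rmse_pct = rmse_from_moments(mu, sigma),
         max_abs_pct = max(abs(diffs)),
         diff_max_pct = diffs[which.max(abs(diffs))],
         n_voxels = length(diffs)),
    class = "diff_report"
  )
}

#' @export
print.diff_report <- function(x, ...) {
  cat(sprintf(
    "<diff_report> mu %.2f%%, sigma %.2f%%, RMSE %.2f%%, max|d| %.2f%% (n=%d)\n",
    x$mu_pct, x$sigma_pct, x$rmse_pct, x$max_abs_pct, x$n_voxels))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the sample standard deviation (divisor
#' `N - 1`: the pairs are a sample).
#'
#' @param a,b Paired measurements (length >= 3 each).
#' @return A `bland_altman` list: `mean_difference`, `loa_low`, `loa_high`,
#'   `n_pairs`, `fraction_within`, plus per-pair `means` and `differences`
#'   for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must match", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  structure(
    list(mean_difference = m, loa_low = lo, loa_high = hi,
         n_pairs = length(d),
         fraction_within = mean(d >= lo & d <= hi),
         means = (a + b) / 2, differences = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean %.4g, LoA [%.4g, %.4g], %d pairs (%.0f%% within)\n",
    x$mean_difference, x$loa_low, x$loa_high, x$n_pairs,
    100 * x$fraction_within))
  invisible(x)
}

#' Ordinary least-squares trend
#'
#' Slope and coefficient of determination of `y ~ x`, used to verify the
#' absence of a Lesion-Error-Ratio trend with lesion diameter.
#'
#' @param x,y Numeric vectors (length >= 3; `x` not constant).
#' @return List with `slope`, `intercept` and `r_squared`.
#' @export
linear_trend <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x)) {
    stop("need >= 3 paired points", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # cor()^2 rather than summary.lm: the latter warns on exact fits
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Bone fraction of a VOI
#'
#' Fraction of masked voxels labelled bone.
#'
#' @param mask Logical VOI mask (non-empty).
#' @param labels Tissue label array ([tissue_codes()]).
#' @return Scalar in \[0, 1\].
#' @export
voi_bone_fraction <- function(mask, labels) {
  if (!any(mask)) stop("empty VOI mask", call. = FALSE)
  mean(labels[mask] == tissue_codes()[["bone"]])
}
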
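#' Tissue label codes
#'
#' Integer codes used in tissue label volumes: 0 air, 1 fat, 2 soft tissue,
#' 3 bone.
#'
#' @return Named integer vector.
#' @export
tissue_codes <- function() {
  c(air = 0L, fat = 1L, soft = 2L, bone = 3L)
}

#' Nominal CT numbers per tissue class
#'
#' Class-representative Hounsfield units used both to synthesise the phantom's
#' CT volume and to calibrate the default Dixon-style segmentation
#' coefficients: air -1000, fat -90, soft tissue +40, bone +700.
#'
#' @return Named numeric vector (HU).
#' @export
nominal_hu <- function() {
  c(air = -1000, fat = -90, soft = 40, bone = 700)
}

# Anatomy model: all lengths are fractions of the reference in-plane FOV so a
# phantom built on any grid keeps its proportions. The reference layout was
# drawn at a 384 mm FOV (128 voxels at 3 mm). Bone structures are deliberately
# slender (thin iliac-wing analogs, a compact acetabular knob and a small
# sacral body): at 511 keV the AC consequence of missing bone scales with the
# cumulative bone chord along each line of response, and an axial pelvis
# slice intersects centimetre-scale, not decimetre-scale, cortical paths.
pelvis_anatomy <- function(fov_mm) {
  s <- min(fov_mm[1:2])
  list(
    body_center = c(0, 0),
    body_semi = c(0.4427, 0.2995) * s,          # outer body ellipse (skin)
    fat_rim_mm = 0.026 * s,                     # subcutaneous fat thickness
    wing_center = c(0.2292, -0.013) * s,        # +/- x: thin iliac wing
    wing_semi = pmax(c(0.0078, 0.0573) * s, c(3, 12)),
    knob_center = c(0.2031, -0.0911) * s,       # +/- x: acetabular knob
    knob_semi = pmax(c(0.0208, 0.0208) * s, 7.5),
    sacrum_center = c(0, -0.1875) * s,          # midline sacral body
    sacrum_semi = pmax(c(0.026, 0.0156) * s, c(7.5, 5))
  )
}

in_ellipse <- function(x, y, center, semi) {
  ((x - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 <= 1
}

#' Generate a synthetic pelvis-like phantom
#'
#' Builds a co-registered tissue label volume, activity volume (kBq/mL) and CT
#' volume (HU) on one grid: an elliptical soft-tissue body with a
#' subcutaneous fat rim, two mirrored lateral bone structures
#' (iliac/acetabular analogs) and a midline bone (sacral analog). Activity is
#' uniform at `background_kbq_ml` in all non-air tissue and exactly zero in
#' air. With `symmetric = TRUE` (the default) labels and activity are exactly
#' invariant under left-right mirroring about the midsagittal plane; with
#' `symmetric = FALSE` the internal structures are jittered independently on
#' the two sides.
#'
#' @param grid A [voxel_grid()] (2-D; a thin third axis replicates the slice).
#' @param background_kbq_ml Background activity concentration, kBq/mL
#'   (non-negative). Default 5.
#' @param seed Integer seed controlling the HU texture and (if asymmetric) the
#'   anatomical jitter; the phantom is bit-reproducible for a fixed seed.
#' @param symmetric Enforce exact bilateral symmetry (default `TRUE`).
#' @param texture_sigma_hu Standard deviation (HU) of the Gaussian texture
#'   added to the nominal class CT numbers; see [labels_to_hu()]. Default 10.
#' @param hu_values Named HU per class, default [nominal_hu()].
#'
#' @return A `phantom_volume`: list with `grid`, `labels` (integer array),
#'   `activity_kbq_ml`, `hu`, plus provenance fields.
#' @examples
#' ph <- make_pelvis_phantom(voxel_grid(c(64, 64), 3), seed = 1)
#' table(ph$labels)
#' @export
make_pelvis_phantom <- function(grid, background_kbq_ml = 5, seed = 1,
                                symmetric = TRUE, texture_sigma_hu = 10,
                                hu_values = nominal_hu()) {
  stopifnot_grid(grid)
  if (!is.finite(background_kbq_ml) || background_kbq_ml < 0) {
    stop("`background_kbq_ml` must be non-negative", call. = FALSE)
  }
  fov <- grid_fov_mm(grid)
  ana <- pelvis_anatomy(fov)
  # the body ellipse must fit inside the grid with an air border
  if (any(2 * ana$body_semi >= fov[1:2] - 2 * grid$voxel_size_mm[1:2])) {
    stop("grid too small to contain the body ellipse with an air border",
         call. = FALSE)
  }
  axes <- grid_axes(grid)
  xm <- midsagittal_x_mm(grid)
  x <- outer(axes[[1]] - xm, rep(1, grid$shape[2]))   # centred on mirror plane
  y <- outer(rep(1, grid$shape[1]), axes[[2]])

  jit <- c(0, 0, 0, 0)
  if (!symmetric) {
    set.seed(derive_seed(seed, 101L))
    jit <- stats::runif(4, -0.015, 0.015) * min(fov[1:2])
  }

  lab <- matrix(tissue_codes()[["air"]], grid$shape[1], grid$shape[2])
  body <- in_ellipse(x, y, ana$body_center, ana$body_semi)
  inner <- in_ellipse(x, y, ana$body_center, ana$body_semi - ana$fat_rim_mm)
  lab[body] <- tissue_codes()[["fat"]]
  lab[inner] <- tissue_codes()[["soft"]]
  wc <- ana$wing_center; kc <- ana$knob_center
  bone <-
    in_ellipse(x, y, c(wc[1] + jit[1], wc[2] + jit[2]), ana$wing_semi) |
    in_ellipse(x, y, c(-wc[1] + jit[3], wc[2] + jit[4]), ana$wing_semi) |
    in_ellipse(x, y, c(kc[1] + jit[1], kc[2] + jit[2]), ana$knob_semi) |
    in_ellipse(x, y, c(-kc[1] + jit[3], kc[2] + jit[4]), ana$knob_semi) |
    in_ellipse(x, y, ana$sacrum_center, ana$sacrum_semi)
  lab[bone & inner] <- tissue_codes()[["bone"]]

  if (symmetric) {
    # exact mirror invariance by construction: left half defines the right
    keep <- seq_len(floor(grid$shape[1] / 2))
    lab[rev(seq_len(grid$shape[1]))[keep], ] <- lab[keep, ]
  }
  storage.mode(lab) <- "integer"

  act <- matrix(0, grid$shape[1], grid$shape[2])
  act[lab != tissue_codes()[["air"]]] <- background_kbq_ml
  hu <- labels_to_hu(lab, seed = seed, texture_sigma_hu = texture_sigma_hu,
                     hu_values = hu_values, grid = grid)
  if (symmetric && texture_sigma_hu > 0) {
    # mirror the texture too so the CT volume shares the label symmetry
    hu <- (hu + mirror_lr(hu)) / 2
  }

  ph <- structure(
    list(grid = grid, labels = lab, activity_kbq_ml = act, hu = hu,
         anatomy = ana, background_kbq_ml = background_kbq_ml,
         seed = as.integer(seed), symmetric = isTRUE(symmetric)),
    class = "phantom_volume"
  )
  validate_phantom(ph)
  ph
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("<phantom_volume> ", paste(x$grid$shape, collapse = " x "),
      " voxels; background ", x$background_kbq_ml, " kBq/mL; ",
      if (x$symmetric) "symmetric" else "asymmetric", "\n", sep = "")
  invisible(x)
}

validate_phantom <- function(ph) {
  codes <- tissue_codes()
  if (!all(ph$labels %in% codes)) stop("invalid tissue codes", call. = FALSE)
  border <- c(ph$labels[1, ], ph$labels[nrow(ph$labels), ],
              ph$labels[, 1], ph$labels[, ncol(ph$labels)])
  if (any(border != codes[["air"]])) {
    stop("outer border voxels must be air", call. = FALSE)
  }
  if (any(ph$activity_kbq_ml < 0)) stop("negative activity", call. = FALSE)
  if (any(ph$activity_kbq_ml[ph$labels == codes[["air"]]] != 0)) {
    stop("air voxels must carry zero activity", call. = FALSE)
  }
  if (any(ph$hu[ph$labels == codes[["air"]]] > -900)) {
    stop("air HU must be <= -900", call. = FALSE)
  }
  if (any(ph$hu[ph$labels == codes[["bone"]]] < 200)) {
    stop("bone HU must be >= +200", call. = FALSE)
  }
  invisible(ph)
}

#' Assign CT numbers to a tissue label volume
#'
#' Maps each tissue class to its nominal HU and optionally adds Gaussian
#' texture (standard deviation `texture_sigma_hu`), clipped so the class
#' invariants hold (air stays below -900 HU, bone above +200 HU, and no
#' texture excursion beyond four standard deviations). Deterministic for a
#' fixed seed.
#'
#' @param labels Integer label array (codes of [tissue_codes()]).
#' @param seed Integer seed for the texture draw.
#' @param texture_sigma_hu Texture standard deviation in HU; 0 gives exactly
#'   the nominal class values.
#' @param hu_values Named HU per class, default [nominal_hu()].
#' @param grid Optional [voxel_grid()] (unused numerically; accepted so
#'   callers can pass a phantom's grid through).
#' @return Numeric array of HU, same shape as `labels`.
#' @export
labels_to_hu <- function(labels, seed = 1, texture_sigma_hu = 0,
                         hu_values = nominal_hu(), grid = NULL) {
  codes <- tissue_codes()
  if (!all(labels %in% codes)) stop("invalid tissue codes", call. = FALSE)
  hu <- array(hu_values[match(as.vector(labels), codes)], dim = dim(labels))
  if (texture_sigma_hu > 0) {
    set.seed(derive_seed(seed, 7L))
    tex <- stats::rnorm(length(labels), sd = texture_sigma_hu)
    tex <- pmin(pmax(tex, -4 * texture_sigma_hu), 4 * texture_sigma_hu)
    hu <- hu + array(tex, dim = dim(labels))
    air <- labels == codes[["air"]]
    bone <- labels == codes[["bone"]]
    hu[air] <- pmin(hu[air], -900)
    hu[bone] <- pmax(hu[bone], 200)
  }
  hu
}

#' Default anatomical target sites
#'
#' Returns the four target-site archetypes used by the targeted insertion
#' study, spanning bone-dominant to soft-tissue-dominant VOI composition:
#' right posterior acetabulum (highest bone fraction), left mid sacrum
#' (intermediate), pelvic sidewall lymph node and posterior bladder (both
#' essentially bone-free). Bone fractions are measured on the phantom with a
#' VOI of `voi_diameter_mm`.
#'
#' @param phantom A `phantom_volume` containing bone.
#' @param voi_diameter_mm VOI diameter used to report each site's bone
#'   fraction (default 12 mm, the targeted-study lesion size).
#' @return List of `target_site` objects (`name`, `center_mm`,
#'   `bone_fraction`).
#' @export
default_target_sites <- function(phantom, voi_diameter_mm = 12) {
  if (!inherits(phantom, "phantom_volume")) {
    stop("`phantom` must be a phantom_volume", call. = FALSE)
  }
  if (!any(phantom$labels == tissue_codes()[["bone"]])) {
    stop("phantom contains no bone; cannot derive target sites",
         call. = FALSE)
  }
  ana <- phantom$anatomy
  s <- min(grid_fov_mm(phantom$grid)[1:2])
  xm <- midsagittal_x_mm(phantom$grid)
  centers <- list(
    # centre of the right acetabular knob: bone-dominant VOI
    acetabulum = ana$knob_center,
    # left part of the sacral body: intermediate bone fraction
    sacrum = c(ana$sacrum_center[1] - 0.6 * ana$sacrum_semi[1],
               ana$sacrum_center[2]),
    # left sidewall soft tissue clear of bone
    lymph_node = c(-0.3073 * s, 0.039 * s),
    # midline soft tissue between bladder and rectum, anterior to the sacrum
    bladder_posterior = c(0, -0.0521 * s)
  )
  sites <- lapply(names(centers), function(nm) {
    ctr <- centers[[nm]] + c(xm, 0)
    mask <- voi_mask(ctr, voi_diameter_mm, phantom$grid)
    structure(
      list(name = nm, center_mm = ctr,
           bone_fraction = voi_bone_fraction(mask, phantom$labels)),
      class = "target_site"
    )
  })
  names(sites) <- names(centers)
  bf <- vapply(sites, `[[`, numeric(1), "bone_fraction")
  if (!(bf[["acetabulum"]] > bf[["sacrum"]] &&
        bf[["sacrum"]] > bf[["lymph_node"]] &&
        bf[["sacrum"]] > bf[["bladder_posterior"]])) {
    stop("site bone fractions not ordered acetabulum > sacrum > soft sites",
         call. = FALSE)
  }
  sites
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site> %s at (%.1f, %.1f) mm; bone fraction %.2f\n",
              x$name, x$center_mm[1], x$center_mm[2], x$bone_fraction))
  invisible(x)
}

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 2011L
}
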
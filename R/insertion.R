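#' Specify a synthetic spherical lesion
#'
#' @param center_mm World coordinates of the lesion centre (mm).
#' @param diameter_mm Lesion diameter (mm), > 0.
#' @param activity_kbq_ml Activity concentration (kBq/mL), > 0.
#' @param id Lesion label (character).
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(center_mm, diameter_mm, activity_kbq_ml,
                        id = "lesion") {
  if (diameter_mm <= 0) stop("diameter must be > 0", call. = FALSE)
  if (activity_kbq_ml <= 0) stop("activity must be > 0", call. = FALSE)
  structure(list(center_mm = as.numeric(center_mm),
                 diameter_mm = as.numeric(diameter_mm),
                 activity_kbq_ml = as.numeric(activity_kbq_ml),
                 id = as.character(id)),
            class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf("<lesion_spec> %s: %g mm, %g kBq/mL at (%s) mm\n", x$id,
              x$diameter_mm, x$activity_kbq_ml,
              paste(signif(x$center_mm, 4), collapse = ", ")))
  invisible(x)
}

#' Rasterize a lesion onto a grid
#'
#' Produces a volume equal to the lesion's activity concentration inside the
#' sphere (disc in 2-D) and zero outside; a voxel is included iff its centre
#' lies within `diameter/2` of the lesion centre — the same rule as
#' [voi_mask()]. A lesion so small that it captures no voxel centre still
#' fills its single nearest voxel, so no insertion is a silent no-op.
#'
#' @param spec A [lesion_spec()].
#' @param grid A [voxel_grid()]; the lesion must lie inside it.
#' @return Numeric activity array (kBq/mL).
#' @export
rasterize_lesion <- function(spec, grid) {
  stopifnot_grid(grid)
  vol <- array(0, dim_of(grid))
  mask <- tryCatch(voi_mask(spec$center_mm, spec$diameter_mm, grid),
                   error = function(e) e)
  if (inherits(mask, "error")) {
    if (grepl("degenerate", conditionMessage(mask))) {
      idx <- round(world_to_index(grid, spec$center_mm))
      idx <- pmin(pmax(idx, 1), matrix(grid$shape, 1))
      vol[matrix(idx, 1)] <- spec$activity_kbq_ml
      return(vol)
    }
    stop(conditionMessage(mask), call. = FALSE)
  }
  vol[mask] <- spec$activity_kbq_ml
  vol
}

#' Insert synthetic lesions into an acquired sinogram
#'
#' Rasterizes and sums the lesions, simulates their acquisition through the
#' same system model as the base acquisition (attenuation from `mu`,
#' normalization, count scale, Poisson noise with the given seed) and adds
#' the lesion sinogram to the base element-wise. The base sinogram is
#' untouched apart from the addition, so the hybrid remains a plausible
#' acquisition of patient-plus-lesions.
#'
#' @param base A [sinogram()] of kind `"counts"` (or `"expected_counts"` for
#'   noiseless studies).
#' @param lesions List of [lesion_spec()] (may be empty).
#' @param grid Image [voxel_grid()].
#' @param mu `mu_map` used to attenuate the lesion data (normally the
#'   ground-truth CTAC map; see [run_matched_study()]).
#' @param norm Optional [normalization_map()].
#' @param count_scale Counts per (kBq/mL x mm); defaults to the base
#'   sinogram's recorded scale.
#' @param seed Seed for the lesion Poisson draw (independent of the base
#'   acquisition's seed).
#' @param noise Poisson noise on the lesion sinogram; defaults to `TRUE`
#'   when the base carries counts, `FALSE` when it carries expectations.
#' @return A [sinogram()] of the same kind as `base`.
#' @export
insert_lesions <- function(base, lesions, grid, mu = NULL, norm = NULL,
                           count_scale = NULL, seed = 1,
                           noise = identical(base$kind, "counts")) {
  if (!inherits(base, "sinogram")) stop("`base` must be a sinogram",
                                        call. = FALSE)
  if (!base$kind %in% c("counts", "expected_counts")) {
    stop("base sinogram must carry counts or expected counts", call. = FALSE)
  }
  if (length(lesions) == 0) return(base)
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  if (is.null(count_scale)) count_scale <- base$scale
  lesion_vol <- Reduce(`+`, lapply(lesions, rasterize_lesion, grid = grid))
  lesion_sino <- simulate_acquisition(
    lesion_vol, grid, mu = mu, norm = norm, geom = base$geometry,
    count_scale = count_scale, seed = seed, noise = noise)
  if (!identical(lesion_sino$kind, base$kind)) {
    lesion_sino$kind <- base$kind     # noiseless insertion into counts data
  }
  add_sinograms(base, lesion_sino)
}

#' Mirror a point about the midsagittal plane
#'
#' Reflects the left-right (x) coordinate about the grid's midsagittal plane
#' ([midsagittal_x_mm()]); all other coordinates, including the axial
#' position, are unchanged. The map is an involution and fixes midline
#' points.
#'
#' @param center_mm World coordinates (mm).
#' @param grid A [voxel_grid()].
#' @return Mirrored world coordinates.
#' @export
contralateral_center <- function(center_mm, grid) {
  stopifnot_grid(grid)
  out <- as.numeric(center_mm)
  out[1] <- 2 * midsagittal_x_mm(grid) - out[1]
  out
}

new_hybrid_study <- function(base_id, lesions, recon_ctac, recon_mrac,
                             seeds) {
  structure(list(base_id = base_id, lesions = lesions,
                 recon_ctac = recon_ctac, recon_mrac = recon_mrac,
                 seeds = seeds),
            class = "hybrid_study")
}

#' Matched contralateral insertion study
#'
#' Runs the first validation protocol on one symmetric phantom: (1) simulate
#' the "original" acquisition of the phantom plus its original lesions;
#' (2) measure each original lesion's mean VOI value on the CTAC
#' reconstruction; (3) insert matched synthetic lesions at the contralateral
#' centres with matched diameter and matched contrast (the measured CTAC mean
#' by default); (4) reconstruct the hybrid with both CTAC and bone-free MRAC
#' from the identical sinogram. Every original/synthetic pair then yields the
#' two SUV Error Ratios and their Lesion Error Ratio.
#'
#' @param phantom A symmetric `phantom_volume`.
#' @param original_lesions List of [lesion_spec()]; all centres off-midline
#'   (a lesion would otherwise overlap its own mirror image).
#' @param geom A [system_geometry()]; default [default_geometry()] of the
#'   phantom grid.
#' @param params A [recon_params()] template (its `mu_map` is replaced by the
#'   per-method maps).
#' @param meta A [scan_meta()] for SUV conversion.
#' @param count_scale Counts per (kBq/mL x mm).
#' @param seed Base seed; acquisition, original-lesion and synthetic-lesion
#'   noise seeds are derived from it independently and recorded.
#' @param noise Poisson noise (default `TRUE`).
#' @param contrast_from `"recon_ctac"` (default: matched contrast is the
#'   original lesion's reconstructed CTAC VOI mean) or `"true"` (the inserted
#'   concentration).
#' @param lesion_mu `"ctac"` (default: inserted lesion data are attenuated by
#'   the ground-truth CTAC map, mimicking physical acquisition) or `"recon"`
#'   (each reconstruction's own hypothesis also attenuates the lesion data).
#' @param keep_images Keep the reconstructed images in the returned studies
#'   (default `FALSE` to bound memory).
#' @return List with `records` (one row per pair: SUV Error Ratios, Lesion
#'   Error Ratio, diameter), `studies`, and `seeds`.
#' @export
run_matched_study <- function(phantom, original_lesions,
                              geom = default_geometry(phantom$grid),
                              params = recon_params(),
                              meta = scan_meta(),
                              count_scale = default_count_scale(),
                              seed = 1, noise = TRUE,
                              contrast_from = c("recon_ctac", "true"),
                              lesion_mu = c("ctac", "recon"),
                              keep_images = FALSE) {
  contrast_from <- match.arg(contrast_from)
  lesion_mu <- match.arg(lesion_mu)
  if (!inherits(phantom, "phantom_volume")) {
    stop("`phantom` must be a phantom_volume", call. = FALSE)
  }
  if (!phantom$symmetric) {
    stop("matched insertion requires a symmetric phantom", call. = FALSE)
  }
  if (inherits(original_lesions, "lesion_spec")) {
    original_lesions <- list(original_lesions)
  }
  grid <- phantom$grid
  xm <- midsagittal_x_mm(grid)
  for (l in original_lesions) {
    if (abs(l$center_mm[1] - xm) < l$diameter_mm / 2) {
      stop("lesion '", l$id, "' lies on the midline; it would overlap its ",
           "mirror image", call. = FALSE)
    }
  }
  mu_ct <- hu_to_mu_ctac(phantom$hu, grid)
  mu_mr <- derive_mrac_dixon(phantom$labels, grid)
  seeds <- list(base = derive_seed(seed, 1L), original = derive_seed(seed, 2L),
                synthetic = derive_seed(seed, 3L))
  base <- simulate_acquisition(phantom$activity_kbq_ml, grid, mu = mu_ct,
                               geom = geom, count_scale = count_scale,
                               seed = seeds$base, noise = noise)
  orig_sino <- insert_lesions(base, original_lesions, grid, mu = mu_ct,
                              count_scale = count_scale,
                              seed = seeds$original, noise = noise)
  p_ct <- params; p_ct$mu_map <- mu_ct
  p_mr <- params; p_mr$mu_map <- mu_mr
  rec_orig_ct <- osem(orig_sino, p_ct, grid)

  synthetic <- lapply(original_lesions, function(l) {
    contrast <- if (contrast_from == "true") {
      l$activity_kbq_ml
    } else {
      mask <- voi_mask(l$center_mm, l$diameter_mm, grid)
      mean(rec_orig_ct$activity_kbq_ml[mask])
    }
    lesion_spec(contralateral_center(l$center_mm, grid), l$diameter_mm,
                contrast, id = paste0(l$id, "_synthetic"))
  })
  # lesion data are attenuated by the ground-truth map; under lesion_mu =
  # "recon" the MRAC branch additionally rebuilds its hybrid with its own map
  hybrid <- insert_lesions(orig_sino, synthetic, grid, mu = mu_ct,
                           count_scale = count_scale, seed = seeds$synthetic,
                           noise = noise)
  rec_ct <- osem(hybrid, p_ct, grid)
  rec_mr <- if (lesion_mu == "recon") {
    hybrid_mr <- insert_lesions(orig_sino, synthetic, grid, mu = mu_mr,
                                count_scale = count_scale,
                                seed = seeds$synthetic, noise = noise)
    osem(hybrid_mr, p_mr, grid)
  } else {
    osem(hybrid, p_mr, grid)
  }

  suv_ct <- to_suv(rec_ct$activity_kbq_ml, meta)
  suv_mr <- to_suv(rec_mr$activity_kbq_ml, meta)
  records <- do.call(rbind, lapply(seq_along(original_lesions), function(i) {
    l <- original_lesions[[i]]
    s <- synthetic[[i]]
    m_o <- voi_mask(l$center_mm, l$diameter_mm, grid)
    m_s <- voi_mask(s$center_mm, s$diameter_mm, grid)
    r_o <- suv_error_ratio(mean(suv_mr[m_o]), mean(suv_ct[m_o]))
    r_s <- suv_error_ratio(mean(suv_mr[m_s]), mean(suv_ct[m_s]))
    data.frame(pair_id = l$id, diameter_mm = l$diameter_mm,
               activity_kbq_ml = l$activity_kbq_ml,
               synthetic_activity_kbq_ml = s$activity_kbq_ml,
               suv_error_ratio_original = r_o,
               suv_error_ratio_synthetic = r_s,
               lesion_error_ratio = lesion_error_ratio(r_o, r_s))
  }))
  study <- new_hybrid_study(
    base_id = sprintf("phantom_seed%d", phantom$seed),
    lesions = c(original_lesions, synthetic),
    recon_ctac = if (keep_images) rec_ct else NULL,
    recon_mrac = if (keep_images) rec_mr else NULL,
    seeds = seeds)
  list(records = records, studies = list(study), seeds = seeds)
}

#' Targeted insertion study
#'
#' Runs the second validation protocol: one fixed-size, fixed-contrast lesion
#' per anatomical target site per phantom (default 12 mm diameter,
#' 5000 kBq/mL), each insertion reconstructed from the identical hybrid
#' sinogram under both CTAC and bone-free MRAC, and the voxel-wise SUV
#' difference percentages summarised per VOI.
#'
#' @param phantoms List of `phantom_volume` (lesion-free backgrounds).
#' @param sites Per-phantom list of target sites, or `NULL` to use
#'   [default_target_sites()] of each phantom.
#' @param diameter_mm Lesion diameter, mm (default 12).
#' @param activity_kbq_ml Lesion activity concentration (default 5000).
#' @param geom,params,meta,count_scale,seed As in [run_matched_study()].
#' @param noise Poisson noise; default `FALSE` (the deterministic protocol
#'   isolates the AC effect from count noise).
#' @param keep_images Keep reconstructed images (default `FALSE`).
#' @return List with `table` (one row per insertion: site, bone fraction,
#'   mu/sigma/RMSE/max of the VOI diff%), `reports` (the `diff_report`s),
#'   `diffs` (per-insertion voxel difference vectors) and `studies`.
#' @export
run_targeted_study <- function(phantoms, sites = NULL, diameter_mm = 12,
                               activity_kbq_ml = 5000,
                               geom = NULL, params = recon_params(),
                               meta = scan_meta(),
                               count_scale = default_count_scale(),
                               seed = 1, noise = FALSE,
                               keep_images = FALSE) {
  if (inherits(phantoms, "phantom_volume")) phantoms <- list(phantoms)
  rows <- list(); reports <- list(); studies <- list(); diffs <- list()
  voi_suv <- list()
  for (pi in seq_along(phantoms)) {
    ph <- phantoms[[pi]]
    grid <- ph$grid
    g <- if (is.null(geom)) default_geometry(grid) else geom
    ph_sites <- if (is.null(sites)) default_target_sites(ph) else sites[[pi]]
    mu_ct <- hu_to_mu_ctac(ph$hu, grid)
    mu_mr <- derive_mrac_dixon(ph$labels, grid)
    p_ct <- params; p_ct$mu_map <- mu_ct
    p_mr <- params; p_mr$mu_map <- mu_mr
    seed_base <- derive_seed(seed, 10L + pi)
    base <- simulate_acquisition(ph$activity_kbq_ml, grid, mu = mu_ct,
                                 geom = g, count_scale = count_scale,
                                 seed = seed_base, noise = noise)
    for (si in seq_along(ph_sites)) {
      site <- ph_sites[[si]]
      mask <- voi_mask(site$center_mm, diameter_mm, grid)
      if (any(ph$activity_kbq_ml[mask] > ph$background_kbq_ml)) {
        stop("target site '", site$name, "' overlaps a pre-existing lesion",
             call. = FALSE)
      }
      les <- lesion_spec(site$center_mm, diameter_mm, activity_kbq_ml,
                         id = sprintf("p%d_%s", pi, site$name))
      seed_les <- derive_seed(seed, 100L * pi + si)
      hybrid <- insert_lesions(base, list(les), grid, mu = mu_ct,
                               count_scale = count_scale, seed = seed_les,
                               noise = noise)
      rec_ct <- osem(hybrid, p_ct, grid)
      rec_mr <- osem(hybrid, p_mr, grid)
      suv_ct <- to_suv(rec_ct$activity_kbq_ml, meta)
      suv_mr <- to_suv(rec_mr$activity_kbq_ml, meta)
      d <- voxel_diff_percent(suv_mr, suv_ct, mask)
      rep <- diff_stats(d)
      key <- les$id
      rows[[key]] <- data.frame(
        phantom = pi, site = site$name,
        bone_fraction = voi_bone_fraction(mask, ph$labels),
        mean_suv_ctac = mean(suv_ct[mask]), mean_suv_mrac = mean(suv_mr[mask]),
        mu_pct = rep$mu_pct, sigma_pct = rep$sigma_pct,
        rmse_pct = rep$rmse_pct, max_abs_pct = rep$max_abs_pct,
        diff_max_pct = rep$diff_max_pct, n_voxels = rep$n_voxels,
        n_excluded = attr(d, "n_excluded"))
      reports[[key]] <- rep
      diffs[[key]] <- as.numeric(d)
      voi_suv[[key]] <- list(phantom = pi, site = site$name,
                             ctac = suv_ct[mask], mrac = suv_mr[mask])
      studies[[key]] <- new_hybrid_study(
        base_id = sprintf("phantom%d", pi), lesions = list(les),
        recon_ctac = if (keep_images) rec_ct else NULL,
        recon_mrac = if (keep_images) rec_mr else NULL,
        seeds = list(base = seed_base, lesion = seed_les))
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, reports = reports, diffs = diffs, voi_suv = voi_suv,
       studies = studies)
}

#' Sample original lesions for a matched study
#'
#' Draws lesion centres in the soft tissue of a symmetric phantom, with the
#' whole lesion inside the body, clear of the midline (so the mirrored
#' synthetic twin cannot overlap), clear of bone, and non-overlapping with
#' the other sampled lesions and their mirror images. Sides alternate
#' (odd-numbered lesions left, even right), emulating the varied
#' lateralization of lesions across a patient cohort. Diameters are drawn
#' uniformly from `diameter_range_mm`.
#'
#' @param phantom A symmetric `phantom_volume`.
#' @param n Number of lesions.
#' @param diameter_range_mm Diameter range, mm (default the 9-40 mm span of
#'   the lesions modelled here).
#' @param activity_kbq_ml Inserted concentration (default 25, a conspicuous
#'   5x background at the default 5 kBq/mL).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per lesion.
#' @return List of [lesion_spec()].
#' @export
sample_original_lesions <- function(phantom, n, diameter_range_mm = c(9, 40),
                                    activity_kbq_ml = 25, seed = 1,
                                    max_tries = 2000) {
  grid <- phantom$grid
  xm <- midsagittal_x_mm(grid)
  ana <- phantom$anatomy
  set.seed(derive_seed(seed, 5L))
  soft <- phantom$labels == tissue_codes()[["soft"]]
  lesions <- list()
  for (i in seq_len(n)) {
    diam <- stats::runif(1, diameter_range_mm[1], diameter_range_mm[2])
    r <- diam / 2
    side <- if (i %% 2 == 1) -1 else 1
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      # uniform in one half of the inner body ellipse's bounding box
      ctr <- c(xm + side *
                 stats::runif(1, r + 3, ana$body_semi[1] - ana$fat_rim_mm),
               stats::runif(1, -1, 1) * (ana$body_semi[2] - ana$fat_rim_mm))
      # whole lesion inside the soft-tissue ellipse
      if (!in_ellipse(ctr[1] - xm, ctr[2], ana$body_center,
                      ana$body_semi - ana$fat_rim_mm - r)) next
      mask <- voi_mask(ctr, diam, grid)
      if (any(phantom$labels[mask] == tissue_codes()[["bone"]])) next
      ok <- TRUE
      for (l in lesions) {
        for (other in list(l$center_mm,
                           contralateral_center(l$center_mm, grid))) {
          if (sqrt(sum((ctr - other)^2)) < r + l$diameter_mm / 2 + 3) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (!ok) next
      lesions[[i]] <- lesion_spec(ctr, diam, activity_kbq_ml,
                                  id = sprintf("les%02d", i))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place lesion ", i, " after ", max_tries, " tries",
           call. = FALSE)
    }
  }
  lesions
}
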
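#' Write and read volumes as NIfTI
#'
#' Volumes are written as `.nii.gz` with the voxel size in the header
#' `pixdim` and the grid recorded in a small JSON sidecar (`<path>.json`) so
#' the world origin round-trips exactly.
#'
#' @param vol Numeric (or integer, e.g. labels) array.
#' @param grid The [voxel_grid()] the volume lives on.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, grid, path) {
  stopifnot_grid(grid)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path)
  sidecar <- list(shape = grid$shape, voxel_size_mm = grid$voxel_size_mm,
                  origin_mm = grid$origin_mm)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @return For `read_volume_nifti()`: list with `vol` and `grid`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  sc <- sidecar_path(path)
  grid <- if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    voxel_grid(meta$shape, meta$voxel_size_mm, meta$origin_mm)
  } else {
    voxel_grid(dim(img), RNifti::pixdim(img))
  }
  list(vol = vol, grid = grid)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write a phantom to a directory
#'
#' Emits `labels.nii.gz`, `activity.nii.gz` and `hu.nii.gz` plus a
#' `phantom.json` provenance sidecar.
#'
#' @param phantom A `phantom_volume`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume_nifti(phantom$labels, phantom$grid,
                     file.path(dir, "labels.nii.gz"))
  write_volume_nifti(phantom$activity_kbq_ml, phantom$grid,
                     file.path(dir, "activity.nii.gz"))
  write_volume_nifti(phantom$hu, phantom$grid, file.path(dir, "hu.nii.gz"))
  jsonlite::write_json(
    list(background_kbq_ml = phantom$background_kbq_ml, seed = phantom$seed,
         symmetric = phantom$symmetric),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read and write lesion lists as CSV
#'
#' Columns: `id, x_mm, y_mm, z_mm, diameter_mm, activity_kbq_ml` (`z_mm` is
#' `NA` for 2-D lesions).
#'
#' @param lesions List of [lesion_spec()].
#' @param path CSV path.
#' @return `write_lesions_csv()` returns `path` invisibly;
#'   `read_lesions_csv()` returns a list of [lesion_spec()].
#' @export
write_lesions_csv <- function(lesions, path) {
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  df <- do.call(rbind, lapply(lesions, function(l) {
    data.frame(id = l$id, x_mm = l$center_mm[1], y_mm = l$center_mm[2],
               z_mm = if (length(l$center_mm) > 2) l$center_mm[3] else NA,
               diameter_mm = l$diameter_mm,
               activity_kbq_ml = l$activity_kbq_ml)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lesions_csv
#' @export
read_lesions_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    ctr <- c(df$x_mm[i], df$y_mm[i])
    if (!is.null(df$z_mm) && !is.na(df$z_mm[i])) ctr <- c(ctr, df$z_mm[i])
    lesion_spec(ctr, df$diameter_mm[i], df$activity_kbq_ml[i], id = df$id[i])
  })
}

#' Write and read sinograms
#'
#' The value array is stored as a plain tab-separated table
#' (angles x radial bins) with the geometry, kind and count scale in a JSON
#' sidecar.
#'
#' @param sino A [sinogram()].
#' @param path Output path (e.g. `sino.tsv`).
#' @return `write_sinogram()` returns `path` invisibly; `read_sinogram()`
#'   returns a [sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  utils::write.table(sino$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(n_angles = sino$geometry$n_angles,
         n_radial_bins = sino$geometry$n_radial_bins,
         radial_spacing_mm = sino$geometry$radial_spacing_mm,
         kind = sino$kind, scale = sino$scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  geom <- system_geometry(meta$n_angles, meta$n_radial_bins,
                          meta$radial_spacing_mm)
  sinogram(geom, vals, meta$kind, scale = meta$scale)
}

#' Write a reconstructed image with its provenance sidecar
#'
#' @param image A `recon_image`.
#' @param path Output `.nii.gz` path; provenance goes to
#'   `<path stem>_provenance.json`.
#' @return `path`, invisibly.
#' @export
write_recon_nifti <- function(image, path) {
  write_volume_nifti(image$activity_kbq_ml, image$grid, path)
  jsonlite::write_json(
    image$provenance,
    paste0(sub("\\.nii(\\.gz)?$", "", path), "_provenance.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
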
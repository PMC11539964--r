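#' Define a voxel grid
#'
#' A `voxel_grid` ties a voxel array to world space: it stores the number of
#' voxels per axis, the voxel size in mm, and the world coordinate (mm) of the
#' centre of the first voxel. The core pipeline is 2-D (a single axial slice);
#' a third axis is accepted for thin-3-D use.
#'
#' @param shape Integer vector (length 2 or 3) of voxel counts per axis; every
#'   count must be at least 8.
#' @param voxel_size_mm Voxel size per axis in mm (recycled to `length(shape)`);
#'   all strictly positive.
#' @param origin_mm World coordinate (mm) of the centre of voxel `(1, 1[, 1])`,
#'   or `NULL` (default) to centre the grid on the world origin, i.e.
#'   `origin = -(shape - 1) / 2 * voxel_size`.
#'
#' @return An object of class `voxel_grid` with elements `shape`,
#'   `voxel_size_mm` and `origin_mm`.
#' @examples
#' g <- voxel_grid(c(128, 128), 3)
#' grid_fov_mm(g)
#' @export
voxel_grid <- function(shape, voxel_size_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L)) {
    stop("`shape` must have length 2 or 3", call. = FALSE)
  }
  if (any(shape < 8L)) stop("all voxel counts must be >= 8", call. = FALSE)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), length(shape))
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0)) {
    stop("all voxel sizes must be positive and finite", call. = FALSE)
  }
  if (is.null(origin_mm)) {
    origin_mm <- -(shape - 1) / 2 * voxel_size_mm
  }
  origin_mm <- rep_len(as.numeric(origin_mm), length(shape))
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm, origin_mm = origin_mm),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

stopifnot_grid <- function(grid) {
  if (!is_voxel_grid(grid)) stop("`grid` must be a voxel_grid", call. = FALSE)
  invisible(grid)
}

#' World and index coordinates on a grid
#'
#' `index_to_world()` maps (1-based) voxel indices to the world coordinates of
#' the voxel centres; `world_to_index()` is its exact inverse (returning
#' fractional, 1-based indices). The two maps compose to the identity.
#'
#' @param grid A [voxel_grid()].
#' @param index Matrix (or vector) of 1-based voxel indices, one row per point.
#' @param world Matrix (or vector) of world coordinates in mm, one row per
#'   point.
#' @return A matrix with one row per point.
#' @export
index_to_world <- function(grid, index) {
  stopifnot_grid(grid)
  index <- coord_matrix(index, length(grid$shape))
  sweep(sweep(index - 1, 2, grid$voxel_size_mm, `*`), 2, grid$origin_mm, `+`)
}

#' @rdname index_to_world
#' @export
world_to_index <- function(grid, world) {
  stopifnot_grid(grid)
  world <- coord_matrix(world, length(grid$shape))
  sweep(sweep(world, 2, grid$origin_mm, `-`), 2, grid$voxel_size_mm, `/`) + 1
}

coord_matrix <- function(x, ndim) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  if (ncol(x) != ndim) {
    stop("coordinate has ", ncol(x), " columns; grid has ", ndim,
         " dimensions", call. = FALSE)
  }
  x
}

#' @rdname index_to_world
#' @export
grid_fov_mm <- function(grid) {
  stopifnot_grid(grid)
  grid$shape * grid$voxel_size_mm
}

#' Voxel-centre coordinate axes
#'
#' World coordinates (mm) of the voxel centres along each axis.
#'
#' @param grid A [voxel_grid()].
#' @return List of numeric vectors, one per axis.
#' @export
grid_axes <- function(grid) {
  stopifnot_grid(grid)
  lapply(seq_along(grid$shape), function(d) {
    grid$origin_mm[d] + (seq_len(grid$shape[d]) - 1) * grid$voxel_size_mm[d]
  })
}

#' Voxel volume (or area, in 2-D) of one voxel
#'
#' @param grid A [voxel_grid()].
#' @return Scalar, in mm^2 (2-D grids) or mm^3.
#' @export
voxel_volume_mm <- function(grid) {
  stopifnot_grid(grid)
  prod(grid$voxel_size_mm)
}

#' World x-coordinate of the midsagittal (left-right mirror) plane
#'
#' Mirroring is about the plane `x = origin_x + (nx - 1) / 2 * dx` in world
#' space, i.e. between the two central voxel columns for even `nx` and through
#' the central column for odd `nx`.
#'
#' @param grid A [voxel_grid()].
#' @return Scalar x-coordinate in mm.
#' @export
midsagittal_x_mm <- function(grid) {
  stopifnot_grid(grid)
  grid$origin_mm[1] + (grid$shape[1] - 1) / 2 * grid$voxel_size_mm[1]
}

#' Mirror a volume about the midsagittal plane
#'
#' Reverses the first (left-right) array dimension; the world-space fixed
#' plane is [midsagittal_x_mm()].
#'
#' @param vol A 2-D or 3-D array.
#' @return The mirrored array.
#' @export
mirror_lr <- function(vol) {
  if (length(dim(vol)) == 2L) {
    vol[rev(seq_len(nrow(vol))), , drop = FALSE]
  } else {
    vol[rev(seq_len(dim(vol)[1])), , , drop = FALSE]
  }
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol
}

grid_key <- function(grid) {
  paste(c(grid$shape, signif(grid$voxel_size_mm, 12),
          signif(grid$origin_mm, 12)), collapse = "|")
}
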
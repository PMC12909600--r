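#' Regular axis-aligned voxel grid
#'
#' Defines the shared geometry for all masks and dose grids: the world
#' position (mm) of the center of voxel (0, 0, 0), the per-axis voxel edge
#' length (mm) and the per-axis voxel counts. Voxel (i, j, k) (0-based) has
#' world center `origin_mm + c(i, j, k) * spacing_mm`. Only axis-aligned
#' grids are supported; orientation ambiguity is deliberately excluded.
#'
#' @param origin_mm Numeric length-3, world coordinate (mm) of the center of
#'   the first voxel.
#' @param spacing_mm Numeric length-3 (or scalar, recycled), strictly
#'   positive voxel edge lengths in mm.
#' @param dims Integer length-3, positive voxel counts per axis.
#' @return A `voxel_grid` object.
#' @examples
#' g <- voxel_grid(c(-50, -50, -50), 2, c(51, 51, 51))
#' voxel_volume_cc(g)
#' @export
voxel_grid <- function(origin_mm, spacing_mm, dims) {
  origin_mm <- as.numeric(origin_mm)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  dims <- as.integer(dims)
  stopifnot(length(origin_mm) == 3L, length(dims) == 3L,
            all(is.finite(origin_mm)), all(is.finite(spacing_mm)))
  if (any(spacing_mm <= 0)) stop("voxel spacing must be strictly positive")
  if (any(dims < 1L)) stop("grid dims must be positive integers")
  structure(list(origin_mm = origin_mm, spacing_mm = spacing_mm, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing_mm), collapse = " x "),
      " mm, origin (", paste(format(x$origin_mm), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' Voxel volume of a grid in cc
#' @param grid A [voxel_grid()].
#' @return Volume of one voxel in cubic centimetres.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing_mm) / 1000

#' World coordinates of voxel centers along one axis
#' @param grid A [voxel_grid()].
#' @param axis Axis index 1, 2 or 3.
#' @return Numeric vector of voxel-center coordinates (mm).
#' @export
grid_axis_mm <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$dims[axis]) - 1L) * grid$spacing_mm[axis]
}

# Full coordinate arrays (column-major; x varies fastest), used by the
# analytic-solid voxelizer and the dose painter.
grid_coord_arrays <- function(grid) {
  d <- grid$dims
  ax <- grid_axis_mm(grid, 1L)
  ay <- grid_axis_mm(grid, 2L)
  az <- grid_axis_mm(grid, 3L)
  list(x = array(ax, dim = d),
       y = array(rep(ay, each = d[1L]), dim = d),
       z = array(rep(az, each = d[1L] * d[2L]), dim = d))
}

#' Test whether two grids share identical geometry
#' @param a,b [voxel_grid()] objects.
#' @param tol Absolute tolerance (mm) on origin and spacing.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol) &&
    all(abs(a$spacing_mm - b$spacing_mm) <= tol)
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop("geometry mismatch: ", what, " are not on the same voxel grid")
  invisible(TRUE)
}

# World-space bounding interval of voxel centers per axis.
grid_bounds_mm <- function(grid) {
  lo <- grid$origin_mm
  hi <- grid$origin_mm + (grid$dims - 1L) * grid$spacing_mm
  rbind(lo = lo, hi = hi)
}
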
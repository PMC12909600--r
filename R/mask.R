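#' Binary structure mask on a voxel grid
#'
#' A named anatomical or planning structure stored as voxel-center occupancy
#' on a [voxel_grid()]. Roles follow the standard lattice-SBRT planning
#' vocabulary: the physician GTV, the raw sphere matrix, the high- and
#' low-dose planning targets, the normal-tissue ring, organs at risk and the
#' body contour.
#'
#' @param grid A [voxel_grid()].
#' @param occupancy Logical array with `dim == grid$dims`.
#' @param name Structure label.
#' @param role One of `"GTV"`, `"SpheresMatrix"`, `"PTV_High"`, `"PTV_Low"`,
#'   `"Ring"`, `"OAR"`, `"Body"`.
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(grid, occupancy, name = role, role = "GTV") {
  role <- match.arg(role, mask_roles())
  occupancy <- as.logical(occupancy)
  if (is.null(dim(occupancy))) dim(occupancy) <- grid$dims
  stopifnot(identical(as.integer(dim(occupancy)), grid$dims))
  occupancy[is.na(occupancy)] <- FALSE
  structure(list(grid = grid, occupancy = occupancy,
                 name = name, role = role),
            class = "structure_mask")
}

#' Recognised structure roles
#' @return Character vector of valid mask roles.
#' @export
mask_roles <- function() {
  c("GTV", "SpheresMatrix", "PTV_High", "PTV_Low", "Ring", "OAR", "Body")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat("<structure_mask> ", x$name, " [", x$role, "], ",
      format(volume_cc(x), digits = 4), " cc on ",
      paste(x$grid$dims, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Structure volume in cc
#' @param mask A [structure_mask()].
#' @return Volume in cubic centimetres (occupied voxels times voxel volume).
#' @export
volume_cc <- function(mask) sum(mask$occupancy) * voxel_volume_cc(mask$grid)

#' @rdname volume_cc
#' @export
is_empty_mask <- function(mask) !any(mask$occupancy)

# Internal voxelwise set algebra; results inherit grid, take name/role of `a`.
mask_and <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  structure_mask(a$grid, a$occupancy & b$occupancy, a$name, a$role)
}
mask_or <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  structure_mask(a$grid, a$occupancy | b$occupancy, a$name, a$role)
}
mask_minus <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  structure_mask(a$grid, a$occupancy & !b$occupancy, a$name, a$role)
}
mask_subset <- function(a, b) all(b$occupancy[a$occupancy])

# Centroid of occupied voxel centers, world mm.
mask_centroid_mm <- function(mask) {
  if (is_empty_mask(mask)) stop("centroid of an empty mask is undefined")
  co <- grid_coord_arrays(mask$grid)
  occ <- mask$occupancy
  c(mean(co$x[occ]), mean(co$y[occ]), mean(co$z[occ]))
}

# World-space bounding box (mm) of occupied voxel centers.
mask_bbox_mm <- function(mask) {
  if (is_empty_mask(mask)) stop("bounding box of an empty mask is undefined")
  occ <- which(mask$occupancy, arr.ind = TRUE) - 1L
  g <- mask$grid
  lo <- g$origin_mm + apply(occ, 2, min) * g$spacing_mm
  hi <- g$origin_mm + apply(occ, 2, max) * g$spacing_mm
  rbind(lo = lo, hi = hi)
}
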
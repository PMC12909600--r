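#' Specification of the high-dose sphere lattice
#'
#' Parameters of the uniform 3D sphere matrix used for lattice (spatially
#' fractionated) SBRT: sphere diameter 10 mm spaced 20 mm center-to-center on
#' a simple-cubic grid, positioned relative to a defined center point, with a
#' cubic matrix extent of 200 mm (expandable to 300 mm for large targets).
#'
#' @param sphere_diameter_mm Sphere diameter, default 10 mm.
#' @param center_spacing_mm Center-to-center spacing, default 20 mm; must be
#'   at least the sphere diameter (non-overlap).
#' @param matrix_extent_mm Cubic matrix edge length per axis (scalar or
#'   length 3), default 200 mm.
#' @param center_point_mm World coordinate (mm) the lattice is centered on,
#'   typically the GTV centroid.
#' @return A `lattice_spec` object.
#' @export
lattice_spec <- function(sphere_diameter_mm = 10, center_spacing_mm = 20,
                         matrix_extent_mm = 200,
                         center_point_mm = c(0, 0, 0)) {
  matrix_extent_mm <- rep_len(as.numeric(matrix_extent_mm), 3L)
  stopifnot(sphere_diameter_mm > 0, all(matrix_extent_mm > 0),
            length(center_point_mm) == 3L)
  if (center_spacing_mm < sphere_diameter_mm)
    stop("overlap error: center spacing (", center_spacing_mm,
         " mm) is below the sphere diameter (", sphere_diameter_mm, " mm)")
  structure(list(sphere_diameter_mm = sphere_diameter_mm,
                 center_spacing_mm = center_spacing_mm,
                 matrix_extent_mm = matrix_extent_mm,
                 center_point_mm = as.numeric(center_point_mm)),
            class = "lattice_spec")
}

new_sphere_set <- function(centers, radius_mm, provenance) {
  structure(list(centers_mm = centers, radius_mm = radius_mm,
                 provenance = provenance),
            class = "sphere_set")
}

#' @export
print.sphere_set <- function(x, ...) {
  cat("<sphere_set> ", nrow(x$centers_mm), " spheres, r = ", x$radius_mm,
      " mm [", x$provenance, "]\n", sep = "")
  invisible(x)
}

#' Number of spheres in a sphere set
#' @param spheres A `sphere_set`.
#' @return Integer count.
#' @export
n_spheres <- function(spheres) nrow(spheres$centers_mm)

#' Generate the uniform sphere lattice
#'
#' Places sphere centers on a simple-cubic grid with step
#' `center_spacing_mm` on each axis, symmetric about `center_point_mm` and
#' covering the full matrix extent inclusive of its boundary planes. The
#' default specification (200 mm extent, 20 mm spacing) yields 11 planes per
#' axis, 1331 candidate spheres. Deterministic.
#'
#' @param spec A [lattice_spec()].
#' @return A `sphere_set` with `centers_mm` (tibble with columns
#'   `x_mm`, `y_mm`, `z_mm`), common `radius_mm` and provenance
#'   `"raw_lattice"`.
#' @export
generate_lattice <- function(spec = lattice_spec()) {
  s <- spec$center_spacing_mm
  offs <- lapply(1:3, function(ax) {
    # enough planes to cover the half-extent, boundary planes included
    nh <- ceiling(spec$matrix_extent_mm[ax] / 2 / s - 1e-9)
    spec$center_point_mm[ax] + s * seq.int(-nh, nh)
  })
  centers <- expand.grid(x_mm = offs[[1L]], y_mm = offs[[2L]],
                         z_mm = offs[[3L]], KEEP.OUT.ATTRS = FALSE)
  centers <- tibble::as_tibble(centers)
  new_sphere_set(centers, spec$sphere_diameter_mm / 2, "raw_lattice")
}

# Voxelize one sphere into logical array; only touches its bounding box.
fill_sphere <- function(occ, grid, center, radius) {
  rng <- lapply(1:3, function(ax) {
    lo <- ceiling((center[ax] - radius - grid$origin_mm[ax]) /
                    grid$spacing_mm[ax])
    hi <- floor((center[ax] + radius - grid$origin_mm[ax]) /
                  grid$spacing_mm[ax])
    seq.int(max(lo, 0L), min(hi, grid$dims[ax] - 1L))
  })
  if (any(lengths(rng) == 0L) ||
      any(vapply(rng, function(r) r[1] > r[length(r)], logical(1))))
    return(occ)
  ax <- grid$origin_mm[1] + rng[[1]] * grid$spacing_mm[1]
  ay <- grid$origin_mm[2] + rng[[2]] * grid$spacing_mm[2]
  az <- grid$origin_mm[3] + rng[[3]] * grid$spacing_mm[3]
  d2 <- outer(outer((ax - center[1])^2, (ay - center[2])^2, `+`),
              (az - center[3])^2, `+`)
  sub <- occ[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L, drop = FALSE]
  occ[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L] <- sub | (d2 <= radius^2)
  occ
}

# Linear voxel indices of one sphere's voxelization (may be empty).
sphere_voxel_idx <- function(grid, center, radius) {
  rng <- lapply(1:3, function(ax) {
    lo <- max(ceiling((center[ax] - radius - grid$origin_mm[ax]) /
                        grid$spacing_mm[ax]), 0)
    hi <- min(floor((center[ax] + radius - grid$origin_mm[ax]) /
                      grid$spacing_mm[ax]), grid$dims[ax] - 1L)
    if (hi < lo) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(rng) == 0L)) return(integer(0))
  ax <- grid$origin_mm[1] + rng[[1]] * grid$spacing_mm[1]
  ay <- grid$origin_mm[2] + rng[[2]] * grid$spacing_mm[2]
  az <- grid$origin_mm[3] + rng[[3]] * grid$spacing_mm[3]
  d2 <- outer(outer((ax - center[1])^2, (ay - center[2])^2, `+`),
              (az - center[3])^2, `+`)
  inside <- which(d2 <= radius^2)
  if (length(inside) == 0L) return(integer(0))
  sub_dims <- lengths(rng)
  idx3 <- arrayInd(inside, sub_dims)
  i <- rng[[1]][idx3[, 1]]; j <- rng[[2]][idx3[, 2]]; k <- rng[[3]][idx3[, 3]]
  as.integer(1L + i + grid$dims[1] * (j + grid$dims[2] * k))
}

#' Voxelize a sphere set
#'
#' Union of the voxel-center voxelizations of every sphere; disjoint spheres
#' contribute additive volume.
#'
#' @param spheres A `sphere_set`.
#' @param grid A [voxel_grid()].
#' @return A [structure_mask()] with role `SpheresMatrix`.
#' @export
voxelize_lattice <- function(spheres, grid) {
  occ <- array(FALSE, grid$dims)
  cm <- as.matrix(spheres$centers_mm)
  for (i in seq_len(nrow(cm)))
    occ <- fill_sphere(occ, grid, cm[i, ], spheres$radius_mm)
  structure_mask(grid, occ, "SpheresMatrix", "SpheresMatrix")
}

#' Crop the sphere lattice to the retracted GTV (PTV_High)
#'
#' Implements the lattice cropping rule: retract the GTV by
#' `retraction_mm` (default 10 mm), keep only spheres that survive the
#' retraction essentially whole, and form PTV_High as the union of the kept
#' spheres. A sphere is kept when at least `completeness_tol` of its
#' voxelized volume lies inside the retracted GTV; this automates the manual
#' deletion of partially cropped spheres. For very small or irregular
#' targets every sphere may be removed; that is a valid (warned) outcome.
#'
#' @param spheres A `sphere_set` (the raw lattice).
#' @param gtv Non-empty GTV [structure_mask()].
#' @param retraction_mm GTV retraction in mm, default 10.
#' @param completeness_tol Surviving-volume fraction required to keep a
#'   sphere, default 0.95.
#' @return List with `ptv_high` ([structure_mask()], role `PTV_High`),
#'   `kept` and `removed` (`sphere_set` objects with provenance
#'   `"cropped"`).
#' @export
crop_to_ptv_high <- function(spheres, gtv, retraction_mm = 10,
                             completeness_tol = 0.95) {
  stopifnot(retraction_mm >= 0, completeness_tol > 0, completeness_tol <= 1)
  if (is_empty_mask(gtv)) stop("GTV is empty; cannot crop the lattice")
  grid <- gtv$grid
  retracted <- suppressWarnings(retract_mask(gtv, retraction_mm))
  cm <- as.matrix(spheres$centers_mm)
  occ <- array(FALSE, grid$dims)
  keep <- logical(nrow(cm))
  for (i in seq_len(nrow(cm))) {
    idx <- sphere_voxel_idx(grid, cm[i, ], spheres$radius_mm)
    if (length(idx) == 0L) next
    surviving <- sum(retracted$occupancy[idx])
    if (surviving >= completeness_tol * length(idx)) {
      keep[i] <- TRUE
      occ[idx] <- TRUE
    }
  }
  if (!any(keep))
    warning("no sphere survived cropping; PTV_High is empty")
  list(ptv_high = structure_mask(grid, occ, "PTV_High", "PTV_High"),
       kept = new_sphere_set(spheres$centers_mm[keep, , drop = FALSE],
                             spheres$radius_mm, "cropped"),
       removed = new_sphere_set(spheres$centers_mm[!keep, , drop = FALSE],
                                spheres$radius_mm, "cropped"))
}

# Smallest default matrix extent (200 then 300 mm) exceeding the GTV
# bounding box plus one lattice spacing on every axis.
auto_matrix_extent <- function(gtv, spacing_mm = 20,
                               candidates_mm = c(200, 300)) {
  bb <- mask_bbox_mm(gtv)
  need <- max(bb["hi", ] - bb["lo", ]) + spacing_mm
  ok <- candidates_mm[candidates_mm >= need]
  if (length(ok) == 0L) {
    warning("GTV exceeds the largest default matrix extent; using ",
            max(candidates_mm), " mm")
    return(max(candidates_mm))
  }
  ok[1L]
}
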
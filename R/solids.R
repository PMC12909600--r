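#' Analytic solid descriptors
#'
#' Simple closed solids used to build synthetic anatomy and the high-dose
#' sphere lattice: spheres, axis-aligned ellipsoids, and "lobed" smooth
#' unions of several ellipsoids (a soft-min blend of their implicit
#' functions, giving the convex-to-lobed character of physician-drawn gross
#' tumor volumes).
#'
#' @param center_mm Numeric length-3 world center (mm).
#' @param radius_mm Sphere radius (mm), `>= 0`.
#' @return A solid descriptor usable with [voxelize_solid()].
#' @name solids
NULL

#' @rdname solids
#' @export
solid_sphere <- function(center_mm, radius_mm) {
  stopifnot(length(center_mm) == 3L, is.finite(radius_mm), radius_mm >= 0)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm),
            class = c("solid_sphere", "solid"))
}

#' @rdname solids
#' @param semiaxes_mm Numeric length-3 ellipsoid semi-axes (mm), `>= 0`.
#' @export
solid_ellipsoid <- function(center_mm, semiaxes_mm) {
  semiaxes_mm <- rep_len(as.numeric(semiaxes_mm), 3L)
  stopifnot(length(center_mm) == 3L, all(is.finite(semiaxes_mm)),
            all(semiaxes_mm >= 0))
  structure(list(center_mm = as.numeric(center_mm), semiaxes_mm = semiaxes_mm),
            class = c("solid_ellipsoid", "solid"))
}

#' @rdname solids
#' @param components List of [solid_ellipsoid()] descriptors to blend.
#' @param blend Soft-min blending parameter (dimensionless, in units of the
#'   normalised implicit function); 0 gives a hard union.
#' @export
solid_lobed <- function(components, blend = 0.2) {
  stopifnot(length(components) >= 1L, blend >= 0)
  ok <- vapply(components, inherits, logical(1), "solid_ellipsoid")
  if (!all(ok)) stop("lobed solid components must be ellipsoids")
  structure(list(components = components, blend = blend),
            class = c("solid_lobed", "solid"))
}

#' @rdname solids
#' @param radius_bot_mm,radius_top_mm Cylinder radii (mm) at the low-z and
#'   high-z ends; unequal radii give a tapered (conical frustum) solid.
#' @param z_min_mm,z_max_mm Axial extent (mm).
#' @export
solid_cylinder <- function(center_mm, radius_bot_mm, radius_top_mm,
                           z_min_mm, z_max_mm) {
  stopifnot(z_max_mm > z_min_mm, radius_bot_mm > 0, radius_top_mm > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_bot_mm = radius_bot_mm, radius_top_mm = radius_top_mm,
                 z_min_mm = z_min_mm, z_max_mm = z_max_mm),
            class = c("solid_cylinder", "solid"))
}

#' @rdname solids
#' @param semiaxes_xy_mm Numeric length-2 cross-sectional semi-axes (mm) of an
#'   elliptic cylinder.
#' @export
solid_elliptic_cylinder <- function(center_mm, semiaxes_xy_mm,
                                    z_min_mm, z_max_mm) {
  stopifnot(z_max_mm > z_min_mm, all(semiaxes_xy_mm > 0))
  structure(list(center_mm = as.numeric(center_mm),
                 semiaxes_xy_mm = as.numeric(semiaxes_xy_mm),
                 z_min_mm = z_min_mm, z_max_mm = z_max_mm),
            class = c("solid_elliptic_cylinder", "solid"))
}

# Implicit membership: TRUE where the point is inside the solid.
solid_contains <- function(solid, x, y, z) UseMethod("solid_contains")

#' @export
solid_contains.solid_sphere <- function(solid, x, y, z) {
  c0 <- solid$center_mm
  (x - c0[1])^2 + (y - c0[2])^2 + (z - c0[3])^2 <= solid$radius_mm^2 &
    solid$radius_mm > 0
}

#' @export
solid_contains.solid_ellipsoid <- function(solid, x, y, z) {
  if (any(solid$semiaxes_mm == 0)) return(rep(FALSE, length(x)))
  c0 <- solid$center_mm; a <- solid$semiaxes_mm
  ((x - c0[1]) / a[1])^2 + ((y - c0[2]) / a[2])^2 +
    ((z - c0[3]) / a[3])^2 <= 1
}

#' @export
solid_contains.solid_lobed <- function(solid, x, y, z) {
  # quasi-SDF per lobe: q_i = sum(((p - c)/a)^2) - 1; blend with soft-min
  qmin <- NULL
  acc <- NULL
  k <- solid$blend
  for (comp in solid$components) {
    c0 <- comp$center_mm; a <- comp$semiaxes_mm
    if (any(a == 0)) next
    q <- ((x - c0[1]) / a[1])^2 + ((y - c0[2]) / a[2])^2 +
      ((z - c0[3]) / a[3])^2 - 1
    if (k > 0) {
      acc <- if (is.null(acc)) exp(-q / k) else acc + exp(-q / k)
    } else {
      qmin <- if (is.null(qmin)) q else pmin(qmin, q)
    }
  }
  if (k > 0) {
    if (is.null(acc)) return(rep(FALSE, length(x)))
    -k * log(acc) <= 0
  } else {
    if (is.null(qmin)) return(rep(FALSE, length(x)))
    qmin <= 0
  }
}

#' @export
solid_contains.solid_cylinder <- function(solid, x, y, z) {
  c0 <- solid$center_mm
  t <- (z - solid$z_min_mm) / (solid$z_max_mm - solid$z_min_mm)
  r <- solid$radius_bot_mm + t * (solid$radius_top_mm - solid$radius_bot_mm)
  inside_z <- z >= solid$z_min_mm & z <= solid$z_max_mm
  inside_z & (x - c0[1])^2 + (y - c0[2])^2 <= r^2
}

#' @export
solid_contains.solid_elliptic_cylinder <- function(solid, x, y, z) {
  c0 <- solid$center_mm; a <- solid$semiaxes_xy_mm
  z >= solid$z_min_mm & z <= solid$z_max_mm &
    ((x - c0[1]) / a[1])^2 + ((y - c0[2]) / a[2])^2 <= 1
}

#' Voxelize an analytic solid
#'
#' A voxel is occupied iff its center lies inside the solid (voxel-center
#' inclusion, no partial-volume weighting). A solid lying entirely outside
#' the grid yields an empty mask with a warning, not an error.
#'
#' @param solid A descriptor from [solid_sphere()], [solid_ellipsoid()],
#'   [solid_lobed()] or the cylinder constructors.
#' @param grid A [voxel_grid()].
#' @param name,role Passed to [structure_mask()].
#' @return A [structure_mask()].
#' @examples
#' g <- voxel_grid(c(-10, -10, -10), 1, c(21, 21, 21))
#' m <- voxelize_solid(solid_sphere(c(0, 0, 0), 5), g)
#' volume_cc(m) # close to 4/3 * pi * 0.5^3
#' @export
voxelize_solid <- function(solid, grid, name = role, role = "GTV") {
  co <- grid_coord_arrays(grid)
  occ <- solid_contains(solid, co$x, co$y, co$z)
  dim(occ) <- grid$dims
  if (!any(occ))
    warning("solid does not cover any voxel center; mask is empty")
  structure_mask(grid, occ, name, role)
}
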
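#' Margin specification for planning-structure derivation
#'
#' Margins (mm) used to derive the planning structures from the GTV: the
#' uniform low-dose target expansion (clinically 3-5 mm), the GTV retraction
#' that confines the high-dose spheres, and the normal-tissue ring width.
#'
#' @param ptv_low_margin_mm Uniform GTV-to-PTV_Low expansion, default 5 mm
#'   (upper end of the clinical 3-5 mm band).
#' @param ptv_high_retraction_mm GTV retraction bounding the kept spheres,
#'   default 10 mm.
#' @param ring_margin_mm Normal-tissue ring width beyond PTV_Low, default
#'   30 mm.
#' @param completeness_tol Fraction of a sphere's voxels that must survive
#'   cropping for the sphere to be kept, default 0.95 (automates the manual
#'   deletion of partially cropped spheres).
#' @return A `derivation_spec` object.
#' @export
derivation_spec <- function(ptv_low_margin_mm = 5,
                            ptv_high_retraction_mm = 10,
                            ring_margin_mm = 30,
                            completeness_tol = 0.95) {
  stopifnot(ptv_low_margin_mm >= 0, ptv_high_retraction_mm >= 0,
            ring_margin_mm >= 0,
            completeness_tol > 0, completeness_tol <= 1)
  structure(list(ptv_low_margin_mm = ptv_low_margin_mm,
                 ptv_high_retraction_mm = ptv_high_retraction_mm,
                 ring_margin_mm = ring_margin_mm,
                 completeness_tol = completeness_tol),
            class = "derivation_spec")
}

#' Uniform Euclidean margin expansion
#'
#' A voxel of the result is occupied iff the Euclidean distance from its
#' center to the nearest occupied voxel center of the input is at most
#' `margin_mm`. Implemented with an exact Euclidean distance transform, so
#' expansion is isotropic even on anisotropic grids. `expand_mask(m, 0)` is
#' the identity. An expansion reaching the grid boundary is silently clipped
#' to the grid (with a warning).
#'
#' @param mask A [structure_mask()].
#' @param margin_mm Margin in mm, `>= 0`.
#' @return Expanded [structure_mask()].
#' @export
expand_mask <- function(mask, margin_mm) {
  stopifnot(margin_mm >= 0)
  if (margin_mm == 0 || is_empty_mask(mask)) return(mask)
  d2 <- edt_sq_cpp(as.logical(mask$occupancy), mask$grid$dims,
                   mask$grid$spacing_mm)
  occ <- array(d2 <= margin_mm^2, mask$grid$dims)
  # warn when the expansion runs into the grid boundary
  b <- mask_bbox_mm(structure_mask(mask$grid, occ, mask$name, mask$role))
  gb <- grid_bounds_mm(mask$grid)
  if (any(b["lo", ] <= gb["lo", ]) || any(b["hi", ] >= gb["hi", ]))
    warning("expansion reaches the grid boundary and is clipped")
  structure_mask(mask$grid, occ, mask$name, mask$role)
}

#' Uniform Euclidean margin retraction
#'
#' A voxel of the result is occupied iff it is occupied in the input and the
#' Euclidean distance from its center to the nearest unoccupied voxel center
#' exceeds `margin_mm`. `retract_mask(m, 0)` is the identity; retraction may
#' legitimately produce an empty mask (small tumors lose all spheres).
#'
#' @inheritParams expand_mask
#' @return Retracted [structure_mask()].
#' @export
retract_mask <- function(mask, margin_mm) {
  stopifnot(margin_mm >= 0)
  if (margin_mm == 0 || is_empty_mask(mask)) return(mask)
  d2 <- edt_sq_cpp(!mask$occupancy, mask$grid$dims, mask$grid$spacing_mm)
  occ <- array(mask$occupancy & d2 > margin_mm^2, mask$grid$dims)
  if (!any(occ)) warning("retraction produced an empty mask")
  structure_mask(mask$grid, occ, mask$name, mask$role)
}

#' Derive the planning structure set from GTV, Body and sphere lattice
#'
#' Builds the standard lattice-SBRT planning structures:
#' `PTV_Low = expand(GTV, margin) n Body`, `PTV_High` from sphere cropping
#' against the retracted GTV (see [crop_to_ptv_high()]), and the
#' normal-tissue `Ring = (expand(PTV_Low, ring) - PTV_Low) n Body`. Derived
#' structures are clipped to the body contour. Containment
#' (`PTV_High < GTV < PTV_Low`, `Ring` disjoint from `PTV_Low`) is verified
#' and violation raises an internal-consistency error.
#'
#' @param gtv,body [structure_mask()] objects on one grid; GTV must lie
#'   inside Body.
#' @param spheres A `sphere_set` from [generate_lattice()] (the raw lattice).
#' @param spec A [derivation_spec()].
#' @return A named list of class `structure_set` with masks `GTV`, `Body`,
#'   `SpheresMatrix`, `PTV_High`, `PTV_Low`, `Ring`, plus attributes
#'   `kept_spheres` and `removed_spheres` ([generate_lattice()] subsets).
#' @export
derive_structures <- function(gtv, body, spheres, spec = derivation_spec()) {
  check_same_grid(gtv$grid, body$grid, "GTV and Body")
  if (!mask_subset(gtv, body))
    stop("internal-consistency error: GTV is not contained in Body")
  matrix_mask <- voxelize_lattice(spheres, gtv$grid)
  crop <- crop_to_ptv_high(spheres, gtv,
                           retraction_mm = spec$ptv_high_retraction_mm,
                           completeness_tol = spec$completeness_tol)
  ptv_low <- mask_and(expand_mask(gtv, spec$ptv_low_margin_mm), body)
  ptv_low$name <- "PTV_Low"; ptv_low$role <- "PTV_Low"
  ring_outer <- suppressWarnings(expand_mask(ptv_low, spec$ring_margin_mm))
  ring <- mask_and(mask_minus(ring_outer, ptv_low), body)
  ring$name <- "Ring"; ring$role <- "Ring"
  ptv_high <- crop$ptv_high
  if (!mask_subset(ptv_high, gtv) || !mask_subset(gtv, ptv_low) ||
      any(ring$occupancy & ptv_low$occupancy))
    stop("internal-consistency error: planning-structure containment violated")
  out <- list(GTV = gtv, Body = body, SpheresMatrix = matrix_mask,
              PTV_High = ptv_high, PTV_Low = ptv_low, Ring = ring)
  attr(out, "kept_spheres") <- crop$kept
  attr(out, "removed_spheres") <- crop$removed
  class(out) <- "structure_set"
  out
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>\n")
  for (nm in names(x))
    cat("  ", format(nm, width = 14), format(volume_cc(x[[nm]]), digits = 4),
        "cc\n")
  invisible(x)
}
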
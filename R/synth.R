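#' Synthetic case specification
#'
#' Describes one synthetic patient: a body contour (elliptic cylinder for
#' thorax, tapered cylinder for extremity), a physician-style GTV (ellipsoid
#' or smooth lobed union of ellipsoids, 40-120 mm extent) and one or two
#' nearby organ-at-risk solids, all voxelized on a regular millimetre-scale
#' grid. Fully deterministic for a fixed seed.
#'
#' @param site `"thorax"` or `"extremity"`.
#' @param gtv_shape `"ellipsoid"` or `"lobed"`.
#' @param gtv_extent_mm Numeric length-3 GTV extent per axis (mm), each in
#'   40-120 (extremity cross-axes must stay within the narrow body).
#' @param oar_offset_mm Gap between the GTV surface and the nearest OAR
#'   surface, default 15 mm.
#' @param spacing_mm Isotropic grid spacing, default 2 mm.
#' @param seed Integer RNG seed.
#' @param case_id Case identifier.
#' @return A `case_spec` object.
#' @export
case_spec <- function(site = c("thorax", "extremity"),
                      gtv_shape = c("ellipsoid", "lobed"),
                      gtv_extent_mm = c(60, 55, 70),
                      oar_offset_mm = 15, spacing_mm = 2, seed = 1,
                      case_id = sprintf("%s_%03d", site[1], seed)) {
  site <- match.arg(site)
  gtv_shape <- match.arg(gtv_shape)
  gtv_extent_mm <- rep_len(as.numeric(gtv_extent_mm), 3L)
  stopifnot(all(gtv_extent_mm >= 40), all(gtv_extent_mm <= 120),
            oar_offset_mm >= 0, spacing_mm > 0)
  structure(list(site = site, gtv_shape = gtv_shape,
                 gtv_extent_mm = gtv_extent_mm,
                 oar_offset_mm = oar_offset_mm, spacing_mm = spacing_mm,
                 seed = as.integer(seed), case_id = case_id),
            class = "case_spec")
}

site_geometry <- function(site, spacing_mm) {
  if (site == "thorax") {
    body <- solid_elliptic_cylinder(c(0, 0, 0), c(150, 100), -120, 120)
    half <- c(156, 106, 126)
  } else {
    body <- solid_cylinder(c(0, 0, 0), 60, 50, -150, 150)
    half <- c(66, 66, 156)
  }
  dims <- 2L * as.integer(floor(half / spacing_mm)) + 1L
  grid <- voxel_grid(-((dims - 1L) / 2) * spacing_mm, spacing_mm, dims)
  list(body = body, grid = grid)
}

build_gtv_solid <- function(spec, center) {
  semi <- spec$gtv_extent_mm / 2
  if (spec$gtv_shape == "ellipsoid")
    return(solid_ellipsoid(center, semi))
  n_lobes <- sample(1:2, 1)
  comps <- list(solid_ellipsoid(center, 0.85 * semi))
  for (l in seq_len(n_lobes)) {
    dirn <- stats::rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
    off <- dirn * 0.45 * semi
    comps[[l + 1L]] <- solid_ellipsoid(center + off, 0.62 * semi)
  }
  solid_lobed(comps, blend = 0.15)
}

#' Generate one synthetic case
#'
#' Voxelizes the body, GTV and OAR solids of a [case_spec()] on the site's
#' grid. The GTV center is jittered a few mm from the body axis (seeded);
#' OARs are spheres placed at the configured offset from the GTV surface.
#' Raises an error when the requested GTV does not fit strictly inside the
#' body.
#'
#' @param spec A [case_spec()].
#' @return A case list with `case_id`, `spec`, `grid` and `masks`
#'   (named [structure_mask()] list: `Body`, `GTV`, `OAR_1`, ...).
#' @export
generate_case <- function(spec) {
  set.seed(spec$seed)
  geo <- site_geometry(spec$site, spec$spacing_mm)
  grid <- geo$grid
  jitter_amp <- if (spec$site == "thorax") 8 else 4
  center <- stats::runif(3, -jitter_amp, jitter_amp)
  center[3] <- center[3] * 2
  gtv_solid <- build_gtv_solid(spec, center)
  body <- voxelize_solid(geo$body, grid, "Body", "Body")
  gtv <- voxelize_solid(gtv_solid, grid, "GTV", "GTV")
  if (is_empty_mask(gtv) || !mask_subset(gtv, body))
    stop("GTV extent too large for the ", spec$site,
         " body; reduce gtv_extent_mm")
  masks <- list(Body = body, GTV = gtv)
  n_oar <- if (spec$site == "thorax") 2L else 1L
  bb <- mask_bbox_mm(gtv)
  oar_r <- 12
  for (k in seq_len(n_oar)) {
    sgn <- if (k == 1L) 1 else -1
    ax <- if (spec$site == "thorax") 2L else 3L
    oc <- center
    oc[ax] <- if (sgn > 0) bb["hi", ax] + spec$oar_offset_mm + oar_r
              else bb["lo", ax] - spec$oar_offset_mm - oar_r
    oar <- voxelize_solid(solid_sphere(oc, oar_r), grid,
                          paste0("OAR_", k), "OAR")
    oar <- mask_and(oar, body)
    oar$name <- paste0("OAR_", k); oar$role <- "OAR"
    masks[[paste0("OAR_", k)]] <- oar
  }
  list(case_id = spec$case_id, spec = spec, grid = grid, masks = masks)
}

#' Generate a synthetic treatment cohort
#'
#' Seeds and sizes a cohort of independent synthetic cases; the default
#' emulates the study population of five thoracic and five extremity
#' patients. Each case gets its own distinct seed derived from the master
#' seed, so the cohort is fully reproducible while cases remain independent.
#' Cases are described (not voxelized) here; [generate_case()] or
#' [run_phase1()] materialises them on demand.
#'
#' @param n_thorax,n_extremity Case counts, default 5 and 5.
#' @param master_seed Integer master seed, default 42.
#' @return Tibble of class `sfrt_cohort` with columns `case_id`, `site`,
#'   `gtv_shape`, `seed`, `ext_x_mm`, `ext_y_mm`, `ext_z_mm` and a
#'   list-column `spec` of [case_spec()] objects.
#' @export
generate_cohort <- function(n_thorax = 5, n_extremity = 5, master_seed = 42) {
  n <- n_thorax + n_extremity
  set.seed(master_seed)
  seeds <- if (n > 0) sample.int(.Machine$integer.max %/% 2, n) else integer(0)
  sites <- rep(c("thorax", "extremity"), c(n_thorax, n_extremity))
  specs <- vector("list", n)
  ext <- matrix(NA_real_, n, 3)
  shapes <- character(n)
  for (i in seq_len(n)) {
    shapes[i] <- if (i %% 2 == 1) "ellipsoid" else "lobed"
    ext[i, ] <- if (sites[i] == "thorax") stats::runif(3, 50, 110)
                else c(stats::runif(2, 45, 78), stats::runif(1, 50, 110))
    specs[[i]] <- case_spec(site = sites[i], gtv_shape = shapes[i],
                            gtv_extent_mm = ext[i, ], seed = seeds[i],
                            case_id = sprintf("case_%02d_%s", i, sites[i]))
  }
  out <- tibble::tibble(
    case_id = vapply(specs, `[[`, character(1), "case_id"),
    site = sites, gtv_shape = shapes,
    seed = if (n > 0) seeds else integer(0),
    ext_x_mm = ext[, 1], ext_y_mm = ext[, 2], ext_z_mm = ext[, 3],
    spec = specs)
  class(out) <- c("sfrt_cohort", class(out))
  out
}

# Separable linear interpolation of a 3D array to a new first-axis length,
# cycling axes with aperm to get full trilinear upsampling.
interp_axis1 <- function(a, n_out) {
  n_in <- dim(a)[1L]
  if (n_in == 1L)
    return(array(rep(a, each = n_out), c(n_out, dim(a)[2:3])))
  u <- seq(0, n_in - 1, length.out = n_out)
  i0 <- pmin(floor(u), n_in - 2)
  w <- u - i0
  a0 <- a[i0 + 1, , , drop = FALSE]
  a1 <- a[i0 + 2, , , drop = FALSE]
  a0 * (1 - w) + a1 * w
}

smooth_random_field <- function(grid, corr_mm = 25) {
  d <- grid$dims
  cdims <- pmax(as.integer(ceiling((d - 1L) * grid$spacing_mm / corr_mm)) + 1L,
                2L)
  ctrl <- array(stats::rnorm(prod(cdims)), cdims)
  f <- ctrl
  for (ax in 1:3) {
    f <- interp_axis1(f, d[ax])
    f <- aperm(f, c(2, 3, 1))
  }
  f
}

#' Smooth random contour perturbation
#'
#' Displaces the mask boundary by a smooth seeded random field with a given
#' RMS magnitude, emulating a re-delineated contour for exercising Dice and
#' mean-surface-distance verification. Implemented as a level-set shift: the
#' voxelized signed distance of the mask is thresholded against a smooth
#' Gaussian random field normalised to unit RMS and scaled by
#' `magnitude_mm`. `magnitude_mm = 0` returns the mask unchanged.
#'
#' @param mask A non-empty [structure_mask()].
#' @param magnitude_mm RMS boundary displacement in mm, `>= 0`.
#' @param seed Integer RNG seed.
#' @return A perturbed [structure_mask()].
#' @export
perturb_contour <- function(mask, magnitude_mm, seed = 1) {
  stopifnot(magnitude_mm >= 0)
  if (magnitude_mm == 0) return(mask)
  if (is_empty_mask(mask)) stop("cannot perturb an empty mask")
  g <- mask$grid
  set.seed(seed)
  f <- smooth_random_field(g)
  f <- f / sqrt(mean(f^2)) * magnitude_mm
  d_out <- sqrt(edt_sq_cpp(as.logical(mask$occupancy), g$dims, g$spacing_mm))
  d_in <- sqrt(edt_sq_cpp(!mask$occupancy, g$dims, g$spacing_mm))
  h2 <- mean(g$spacing_mm) / 2
  phi <- ifelse(mask$occupancy, -(d_in - h2), d_out - h2)
  structure_mask(g, array(phi <= f, g$dims), mask$name, mask$role)
}
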
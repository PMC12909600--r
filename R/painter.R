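#' Two-phase prescription regimen
#'
#' The lattice-SBRT regimen: Phase 1 delivers a single fraction with 12 Gy
#' to the high-dose sphere lattice and 4 Gy to the GTV-level target, Phase 2
#' delivers four further fractions of 4 Gy to PTV_Low, totalling 20 Gy to
#' the GTV/PTV_Low region. Plan hotspots are capped at 15 Gy (125% of the
#' sphere dose).
#'
#' @param phase1_sphere_dose_gy Sphere (PTV_High) dose in Phase 1, default
#'   12 Gy.
#' @param phase1_gtv_dose_gy GTV/PTV_Low-level dose in Phase 1, default 4 Gy.
#' @param phase2_fraction_dose_gy Dose per Phase 2 fraction, default 4 Gy.
#' @param phase2_n_fractions Number of Phase 2 fractions, default 4.
#' @param hotspot_cap_gy Global maximum allowed dose, default 15 Gy.
#' @return A `regimen_spec` object.
#' @export
regimen_spec <- function(phase1_sphere_dose_gy = 12, phase1_gtv_dose_gy = 4,
                         phase2_fraction_dose_gy = 4, phase2_n_fractions = 4,
                         hotspot_cap_gy = 15) {
  stopifnot(phase1_sphere_dose_gy > 0, phase1_gtv_dose_gy > 0,
            phase2_fraction_dose_gy >= 0, phase2_n_fractions >= 0)
  if (hotspot_cap_gy < phase1_sphere_dose_gy)
    stop("hotspot cap must be at least the sphere dose")
  structure(list(phase1_sphere_dose_gy = phase1_sphere_dose_gy,
                 phase1_gtv_dose_gy = phase1_gtv_dose_gy,
                 phase2_fraction_dose_gy = phase2_fraction_dose_gy,
                 phase2_n_fractions = phase2_n_fractions,
                 hotspot_cap_gy = hotspot_cap_gy),
            class = "regimen_spec")
}

#' Parameters of the kernel dose painter
#'
#' The painter is an openly simplified stand-in for a treatment planning
#' optimizer: it constructs dose fields from radial kernels with hard caps
#' so that well-formed geometries satisfy the planning objectives by
#' construction. It makes no claim of beam-physics realism.
#'
#' @param penumbra_sigma_mm Gaussian falloff scale of the dose bath outside
#'   PTV_Low, default 4 mm.
#' @param boost_kernel_sigma_mm Gaussian shoulder scale of each sphere boost
#'   outside the sphere surface, default 4 mm.
#' @param ring_cap_gy Hard cap on dose outside PTV_Low, default 4 Gy
#'   (the normal-tissue ring objective).
#' @return A `painter_params` object.
#' @export
painter_params <- function(penumbra_sigma_mm = 4, boost_kernel_sigma_mm = 4,
                           ring_cap_gy = 4) {
  stopifnot(penumbra_sigma_mm > 0, boost_kernel_sigma_mm > 0, ring_cap_gy > 0)
  structure(list(penumbra_sigma_mm = penumbra_sigma_mm,
                 boost_kernel_sigma_mm = boost_kernel_sigma_mm,
                 ring_cap_gy = ring_cap_gy),
            class = "painter_params")
}

# Base bath: plateau inside PTV_Low, Gaussian falloff of the Euclidean
# distance outside, hard-capped at ring_cap beyond the target.
paint_base <- function(ptv_low, plateau_gy, params) {
  g <- ptv_low$grid
  d2 <- edt_sq_cpp(as.logical(ptv_low$occupancy), g$dims, g$spacing_mm)
  base <- plateau_gy * exp(-d2 / (2 * params$penumbra_sigma_mm^2))
  outside <- !ptv_low$occupancy
  base[outside] <- pmin(base[outside], params$ring_cap_gy)
  base[ptv_low$occupancy] <- plateau_gy
  array(base, g$dims)
}

# Per-sphere boost kernel: flat plateau at the sphere dose inside the
# sphere, Gaussian shoulder of distance-to-surface outside; combined across
# spheres by voxelwise maximum.
paint_boost <- function(spheres, grid, sphere_dose_gy, sigma_mm) {
  boost <- array(0, grid$dims)
  cm <- as.matrix(spheres$centers_mm)
  r_s <- spheres$radius_mm
  reach <- r_s + 5 * sigma_mm
  for (i in seq_len(nrow(cm))) {
    center <- cm[i, ]
    rng <- lapply(1:3, function(ax) {
      lo <- max(ceiling((center[ax] - reach - grid$origin_mm[ax]) /
                          grid$spacing_mm[ax]), 0)
      hi <- min(floor((center[ax] + reach - grid$origin_mm[ax]) /
                        grid$spacing_mm[ax]), grid$dims[ax] - 1L)
      if (hi < lo) integer(0) else seq.int(lo, hi)
    })
    if (any(lengths(rng) == 0L)) next
    ax <- grid$origin_mm[1] + rng[[1]] * grid$spacing_mm[1]
    ay <- grid$origin_mm[2] + rng[[2]] * grid$spacing_mm[2]
    az <- grid$origin_mm[3] + rng[[3]] * grid$spacing_mm[3]
    r <- sqrt(outer(outer((ax - center[1])^2, (ay - center[2])^2, `+`),
                    (az - center[3])^2, `+`))
    k <- ifelse(r <= r_s, sphere_dose_gy,
                sphere_dose_gy * exp(-(r - r_s)^2 / (2 * sigma_mm^2)))
    sub <- boost[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L, drop = FALSE]
    boost[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L] <- pmax(sub, k)
  }
  boost
}

#' Paint the Phase 1 lattice plan
#'
#' Deterministic construction of the Phase 1 dose: a GTV-level dose bath
#' (plateau inside PTV_Low with a capped Gaussian penumbra outside) plus
#' per-sphere boost kernels that hold every voxel of each kept sphere at the
#' sphere prescription. Base and boost are combined by voxelwise maximum
#' inside the GTV; outside the GTV only the base bath applies, which keeps
#' dose spill outside the target capped by construction. The result is
#' checked against the hotspot cap, the sphere-coverage floor and the
#' outside-target cap, and painting fails loudly (with the violated
#' constraint named) rather than silently degrading coverage.
#'
#' @param structures A `structure_set` from [derive_structures()].
#' @param spheres The kept `sphere_set` (e.g.
#'   `attr(structures, "kept_spheres")`); may be empty, giving a pure base
#'   plan.
#' @param regimen A [regimen_spec()].
#' @param params A [painter_params()].
#' @return A [dose_grid()] labelled `"phase1"`.
#' @export
paint_phase1 <- function(structures, spheres = attr(structures, "kept_spheres"),
                         regimen = regimen_spec(), params = painter_params()) {
  ptv_low <- structures$PTV_Low
  gtv <- structures$GTV
  if (is_empty_mask(ptv_low)) stop("PTV_Low is empty; nothing to paint")
  g <- ptv_low$grid
  base <- paint_base(ptv_low, regimen$phase1_gtv_dose_gy, params)
  dose <- base
  if (!is.null(spheres) && n_spheres(spheres) > 0L) {
    boost <- paint_boost(spheres, g, regimen$phase1_sphere_dose_gy,
                         params$boost_kernel_sigma_mm)
    inside <- gtv$occupancy
    dose[inside] <- pmax(base[inside], boost[inside])
  }
  tol <- 1e-9
  if (max(dose) > regimen$hotspot_cap_gy + tol)
    stop("constructive failure: hotspot cap ", regimen$hotspot_cap_gy,
         " Gy exceeded (max ", format(max(dose), digits = 6), " Gy)")
  if (!is.null(spheres) && n_spheres(spheres) > 0L) {
    cm <- as.matrix(spheres$centers_mm)
    for (i in seq_len(nrow(cm))) {
      idx <- sphere_voxel_idx(g, cm[i, ], spheres$radius_mm)
      if (length(idx) == 0L) next
      dmin <- min(dose[idx])
      if (dmin < regimen$phase1_sphere_dose_gy - tol)
        stop("constructive failure: sphere coverage floor ",
             regimen$phase1_sphere_dose_gy, " Gy violated (min ",
             format(dmin, digits = 6), " Gy in sphere ", i,
             "; is the sphere inside the GTV?)")
    }
  }
  spill <- max(dose[!ptv_low$occupancy])
  if (spill > params$ring_cap_gy + tol)
    stop("constructive failure: dose outside PTV_Low exceeds the ",
         params$ring_cap_gy, " Gy cap (max ", format(spill, digits = 6), ")")
  dose_grid(g, dose, "phase1")
}

#' Paint one Phase 2 fraction
#'
#' Uniform fraction dose inside PTV_Low with the same capped Gaussian
#' penumbra outside. Deterministic.
#'
#' @inheritParams paint_phase1
#' @return A [dose_grid()] labelled `"phase2_fraction"`.
#' @export
paint_phase2 <- function(structures, regimen = regimen_spec(),
                         params = painter_params()) {
  ptv_low <- structures$PTV_Low
  if (is_empty_mask(ptv_low)) stop("PTV_Low is empty; nothing to paint")
  dose <- paint_base(ptv_low, regimen$phase2_fraction_dose_gy, params)
  dose_grid(ptv_low$grid, dose, "phase2_fraction")
}
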
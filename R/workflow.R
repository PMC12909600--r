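#' Workflow configuration
#'
#' Bundles every tunable of the end-to-end pipeline with its default:
#' lattice geometry, margin derivation, prescription regimen, painter
#' parameters, objective set, gamma criteria, and the contour-surrogate
#' perturbation magnitude.
#'
#' @param lattice_diameter_mm,lattice_spacing_mm Sphere diameter and
#'   center-to-center spacing, defaults 10 and 20 mm.
#' @param derivation A [derivation_spec()].
#' @param regimen A [regimen_spec()].
#' @param painter A [painter_params()].
#' @param objectives An objective set from [sfrt_objectives()]; the strict
#'   clinical-acceptance variant is the default gate for the
#'   adaptive-or-nothing rule.
#' @param gamma A [gamma_criteria()].
#' @param contour_perturb_mm RMS magnitude of the re-contouring surrogate,
#'   default 1 mm.
#' @param recalc_scale,recalc_shift_mm Perturbation applied to form the
#'   secondary-verification recomputation (global dose rescale and rigid
#'   shift), defaults 1.02 and 1 mm.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(lattice_diameter_mm = 10, lattice_spacing_mm = 20,
                            derivation = derivation_spec(),
                            regimen = regimen_spec(),
                            painter = painter_params(),
                            objectives = sfrt_objectives(strict = TRUE),
                            gamma = gamma_criteria(),
                            contour_perturb_mm = 1,
                            recalc_scale = 1.02, recalc_shift_mm = 1) {
  structure(list(lattice_diameter_mm = lattice_diameter_mm,
                 lattice_spacing_mm = lattice_spacing_mm,
                 derivation = derivation, regimen = regimen,
                 painter = painter, objectives = objectives, gamma = gamma,
                 contour_perturb_mm = contour_perturb_mm,
                 recalc_scale = recalc_scale,
                 recalc_shift_mm = recalc_shift_mm),
            class = "workflow_config")
}

# Perturbed independent recomputation used for secondary verification:
# global rescale plus a rigid origin shift along x.
recalc_dose <- function(dose, scale = 1.02, shift_mm = 1) {
  g <- dose$grid
  g2 <- voxel_grid(g$origin_mm + c(shift_mm, 0, 0), g$spacing_mm, g$dims)
  dose_grid(g2, dose$dose_gy * scale, dose$phase_label)
}

#' Run the Phase 1 pipeline for one case
#'
#' Executes the full single-session chain on a synthetic case: lattice
#' generation (sized and centered on the GTV), planning-structure
#' derivation with sphere cropping, a re-contouring surrogate verified by
#' Dice/mean-surface-distance, Phase 1 dose painting, objective checking,
#' and gamma-based secondary verification against a perturbed recomputation.
#' Under the adaptive-or-nothing rule the case fails (and carries no dose)
#' unless every objective passes. Per-step compute wall times are logged;
#' they cover computation only, not any human workflow step.
#'
#' @param case A [case_spec()] or a generated case from [generate_case()].
#' @param config A [workflow_config()].
#' @return A `phase1_result` with `case_id`, `structures`, `spheres`
#'   (kept), `dose` (`NULL` when the case fails), `report`
#'   ([check_objectives()] output), `contour_qc` (tibble with `dice`,
#'   `msd_mm`), `gamma` (a `gamma_result`, only when passing), `timing`
#'   (tibble `step`, `seconds`) and `pass`.
#' @export
run_phase1 <- function(case, config = workflow_config()) {
  if (inherits(case, "case_spec")) case <- generate_case(case)
  timing <- list()
  tic <- function(expr) system.time(expr, gcFirst = FALSE)[["elapsed"]]
  gtv <- case$masks$GTV
  body <- case$masks$Body

  timing$lattice_generation <- tic({
    spec <- lattice_spec(
      sphere_diameter_mm = config$lattice_diameter_mm,
      center_spacing_mm = config$lattice_spacing_mm,
      matrix_extent_mm = auto_matrix_extent(gtv, config$lattice_spacing_mm),
      center_point_mm = mask_centroid_mm(gtv))
    spheres <- generate_lattice(spec)
  })
  timing$reference_derivation <- tic({
    structures <- derive_structures(gtv, body, spheres, config$derivation)
  })
  timing$adaptive_contouring_surrogate <- tic({
    recontoured <- perturb_contour(gtv, config$contour_perturb_mm,
                                   seed = case$spec$seed + 1L)
    contour_qc <- tibble::tibble(dice = dice(gtv, recontoured),
                                 msd_mm = mean_surface_distance(gtv,
                                                                recontoured))
  })
  timing$plan_painting <- tic({
    dose <- paint_phase1(structures, attr(structures, "kept_spheres"),
                         config$regimen, config$painter)
  })
  timing$evaluation <- tic({
    report <- check_objectives(dose, structures, config$objectives)
  })
  pass <- attr(report, "overall_pass")
  gam <- NULL
  if (pass) {
    timing$gamma_qa <- tic({
      gam <- gamma_3d(dose, recalc_dose(dose, config$recalc_scale,
                                        config$recalc_shift_mm),
                      config$gamma)
    })
  }
  structure(list(case_id = case$case_id,
                 structures = structures,
                 spheres = attr(structures, "kept_spheres"),
                 dose = if (pass) dose else NULL,
                 report = report, contour_qc = contour_qc, gamma = gam,
                 timing = tibble::tibble(step = names(timing),
                                         seconds = unlist(timing,
                                                          use.names = FALSE)),
                 pass = pass),
            class = "phase1_result")
}

#' @export
print.phase1_result <- function(x, ...) {
  cat("<phase1_result> ", x$case_id, ": ",
      if (x$pass) "PASS" else "FAIL", ", ", n_spheres(x$spheres),
      " spheres kept\n", sep = "")
  invisible(x)
}

#' Run Phase 2 and accumulate the course dose
#'
#' Paints the Phase 2 fractions (uniform PTV_Low dose), accumulates them
#' with the Phase 1 plan, and reports total-dose metrics. Requires a passing
#' Phase 1 result.
#'
#' @param phase1 A passing `phase1_result`.
#' @param config A [workflow_config()].
#' @param n_fractions Number of fractions, default from the regimen.
#' @return List with `total` ([dose_grid()]), `fraction` (one painted
#'   fraction), and `summary` (tibble of total-dose metrics, including the
#'   GTV-centroid dose that realises the 20 Gy course prescription).
#' @export
run_phase2 <- function(phase1, config = workflow_config(),
                       n_fractions = config$regimen$phase2_n_fractions) {
  if (is.null(phase1$dose))
    stop("Phase 1 did not pass (or was not run); Phase 2 requires its dose")
  frac <- paint_phase2(phase1$structures, config$regimen, config$painter)
  total <- accumulate_dose(c(list(phase1$dose),
                             rep(list(frac), n_fractions)))
  # course dose at GTV level, sampled outside the boosted spheres where the
  # 20 Gy GTV/PTV_Low prescription applies
  gtv_bath <- mask_minus(phase1$structures$GTV, phase1$structures$PTV_High)
  summary <- tibble::tibble(
    metric = c("gtv_bath_median_dose_gy", "ptv_low_dmean_gy",
               "ptv_low_d95_gy"),
    value = c(stats::median(total$dose_gy[gtv_bath$occupancy]),
              mean_dose(total, phase1$structures$PTV_Low),
              dose_at_volume(total, phase1$structures$PTV_Low,
                             volume_pct = 95)))
  list(total = total, fraction = frac, summary = summary)
}

#' Run the whole cohort
#'
#' Runs [run_phase1()] for every case of a cohort and tabulates per-case
#' outcomes, key metrics and per-step compute times. A failing case is
#' recorded, not fatal.
#'
#' @param cohort An `sfrt_cohort` from [generate_cohort()].
#' @param config A [workflow_config()].
#' @param keep_results Keep the full per-case `phase1_result` objects in the
#'   `results` attribute (memory-heavy), default `FALSE`.
#' @return Tibble with one row per case: `case_id`, `site`, `pass`,
#'   `n_spheres_kept`, `ptv_high_v12_pct`, `ptv_high_d003cc_gy`,
#'   `ptv_low_v4_pct`, `ptv_low_d003cc_gy`, `ptv_low_dmean_gy`,
#'   `ring_d003cc_gy`, `gamma_pass_pct`, `dice`, `msd_mm`, `total_seconds`.
#' @export
run_cohort <- function(cohort, config = workflow_config(),
                       keep_results = FALSE) {
  results <- vector("list", nrow(cohort))
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    res <- tryCatch(run_phase1(cohort$spec[[i]], config),
                    error = function(e) e)
    if (inherits(res, "error"))
      return(tibble::tibble(case_id = cohort$case_id[i],
                            site = cohort$site[i], pass = FALSE,
                            n_spheres_kept = NA_integer_,
                            ptv_high_v12_pct = NA_real_,
                            ptv_high_d003cc_gy = NA_real_,
                            ptv_low_v4_pct = NA_real_,
                            ptv_low_d003cc_gy = NA_real_,
                            ptv_low_dmean_gy = NA_real_,
                            ring_d003cc_gy = NA_real_,
                            gamma_pass_pct = NA_real_, dice = NA_real_,
                            msd_mm = NA_real_, total_seconds = NA_real_,
                            error = conditionMessage(res)))
    if (keep_results) results[[i]] <<- res
    metric <- function(s, m) {
      r <- res$report
      v <- r$value[r$structure == s & r$metric == m]
      if (length(v) == 1L) v else NA_real_
    }
    tibble::tibble(case_id = res$case_id, site = cohort$site[i],
                   pass = res$pass,
                   n_spheres_kept = n_spheres(res$spheres),
                   ptv_high_v12_pct = metric("PTV_High", "V12Gy"),
                   ptv_high_d003cc_gy = metric("PTV_High", "D0.03cc"),
                   ptv_low_v4_pct = if (is.null(res$dose)) NA_real_ else
                     volume_at_dose(res$dose, res$structures$PTV_Low, 4),
                   ptv_low_d003cc_gy = metric("PTV_Low", "D0.03cc"),
                   ptv_low_dmean_gy = metric("PTV_Low", "Dmean"),
                   ring_d003cc_gy = metric("Ring", "D0.03cc"),
                   gamma_pass_pct = if (is.null(res$gamma)) NA_real_
                                    else res$gamma$pass_rate_pct,
                   dice = res$contour_qc$dice,
                   msd_mm = res$contour_qc$msd_mm,
                   total_seconds = sum(res$timing$seconds),
                   error = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  if (keep_results) attr(out, "results") <- results
  out
}
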
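#' Gamma-analysis criteria
#'
#' Dose-difference / distance-to-agreement criteria for 3D gamma comparison.
#' Two presets are in clinical use here: 3%/2 mm (plan-acceptance criterion)
#' and 5%/3 mm (secondary-verification reporting), both with a 10% low-dose
#' threshold and a 90% pass-rate expectation. Dose difference is global
#' (percent of the reference maximum) unless `local_norm = TRUE`.
#'
#' @param dose_diff_pct Dose-difference criterion in percent, default 5.
#' @param dta_mm Distance-to-agreement criterion in mm, default 3.
#' @param low_dose_threshold_pct Reference voxels below this percent of the
#'   reference maximum are excluded from analysis, default 10.
#' @param local_norm Normalise the dose difference to the local reference
#'   dose instead of the global maximum, default `FALSE`.
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dose_diff_pct = 5, dta_mm = 3,
                           low_dose_threshold_pct = 10, local_norm = FALSE) {
  stopifnot(dose_diff_pct > 0, dta_mm > 0, low_dose_threshold_pct > 0)
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 local_norm = isTRUE(local_norm)),
            class = "gamma_criteria")
}

#' @rdname gamma_criteria
#' @param preset `"5/3"` (verification reporting) or `"3/2"`
#'   (plan-acceptance).
#' @export
gamma_preset <- function(preset = c("5/3", "3/2")) {
  preset <- match.arg(preset)
  if (preset == "5/3") gamma_criteria(5, 3, 10) else gamma_criteria(3, 2, 10)
}

#' 3D gamma-index dose comparison
#'
#' For every reference voxel at or above the low-dose threshold, the gamma
#' index is the minimum over nearby evaluated-dose samples of
#' `sqrt((dr/DTA)^2 + (dD/(diff% x Dref_max))^2)`, searched over a
#' distance-sorted pattern of displacements with radius `3 x DTA` and step
#' half the smaller of the evaluated voxel spacing and the DTA, with the
#' evaluated dose trilinearly interpolated. The pass rate is the percent of
#' analysed voxels with gamma at or below 1. The grids of the two doses may
#' differ (the evaluated grid may be finer or rigidly shifted) but must
#' overlap.
#'
#' @param reference,evaluated [dose_grid()] objects; `reference` defines the
#'   analysed voxels and the global normalisation.
#' @param criteria A [gamma_criteria()].
#' @return A `gamma_result` with the per-voxel `gamma` array (`NA` below
#'   threshold), `pass_rate_pct`, `n_evaluated` and the criteria. See
#'   [glance.gamma_result()].
#' @export
gamma_3d <- function(reference, evaluated, criteria = gamma_criteria()) {
  dmax <- max(reference$dose_gy)
  if (dmax <= 0) stop("reference dose maximum must be positive")
  rb <- grid_bounds_mm(reference$grid)
  eb <- grid_bounds_mm(evaluated$grid)
  if (any(rb["hi", ] < eb["lo", ]) || any(eb["hi", ] < rb["lo", ]))
    stop("reference and evaluated grids do not overlap")
  step <- min(min(evaluated$grid$spacing_mm), criteria$dta_mm) / 2
  gam <- gamma_core_cpp(
    reference$dose_gy, reference$grid$dims,
    reference$grid$origin_mm, reference$grid$spacing_mm,
    evaluated$dose_gy, evaluated$grid$dims,
    evaluated$grid$origin_mm, evaluated$grid$spacing_mm,
    criteria$dose_diff_pct / 100, dmax, criteria$dta_mm,
    criteria$low_dose_threshold_pct / 100 * dmax,
    3 * criteria$dta_mm, step, criteria$local_norm)
  vals <- gam[!is.na(gam)]
  structure(list(gamma = gam,
                 pass_rate_pct = if (length(vals)) 100 * mean(vals <= 1)
                                 else NA_real_,
                 n_evaluated = length(vals),
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cr <- x$criteria
  cat("<gamma_result> ", format(x$pass_rate_pct, digits = 4), "% pass (",
      x$n_evaluated, " voxels, ", cr$dose_diff_pct, "%/", cr$dta_mm,
      " mm, ", cr$low_dose_threshold_pct, "% threshold)\n", sep = "")
  invisible(x)
}
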
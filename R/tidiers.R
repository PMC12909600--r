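#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an objective-check report
#'
#' @param x A `metric_report` from [check_objectives()].
#' @param ... Unused.
#' @return A plain tibble with one row per objective.
#' @export
tidy.metric_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "metric_report")
  attr(out, "overall_pass") <- NULL
  out
}

#' @rdname tidy.metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(n_objectives = nrow(x), n_pass = sum(x$pass),
                 overall_pass = all(x$pass))
}

#' Tidy a gamma-analysis result
#'
#' @param x A `gamma_result` from [gamma_3d()].
#' @param ... Unused.
#' @return `tidy()`: one row per analysed voxel (`gamma`); `glance()`: a
#'   one-row summary with the pass rate, analysed-voxel count and criteria.
#' @export
tidy.gamma_result <- function(x, ...) {
  tibble::tibble(gamma = x$gamma[!is.na(x$gamma)])
}

#' @rdname tidy.gamma_result
#' @export
glance.gamma_result <- function(x, ...) {
  cr <- x$criteria
  tibble::tibble(pass_rate_pct = x$pass_rate_pct, n_evaluated = x$n_evaluated,
                 mean_gamma = mean(x$gamma, na.rm = TRUE),
                 dose_diff_pct = cr$dose_diff_pct, dta_mm = cr$dta_mm,
                 low_dose_threshold_pct = cr$low_dose_threshold_pct)
}

#' Tidy a sphere set
#'
#' @param x A `sphere_set`.
#' @param ... Unused.
#' @return Tibble of sphere centers (mm) with the common radius.
#' @export
tidy.sphere_set <- function(x, ...) {
  dplyr::mutate(x$centers_mm, radius_mm = x$radius_mm)
}

#' Tidy a Phase 1 pipeline result
#'
#' @param x A `phase1_result` from [run_phase1()].
#' @param ... Unused.
#' @return `tidy()`: the objective report; `glance()`: one-row case summary.
#' @export
tidy.phase1_result <- function(x, ...) tidy(x$report)

#' @rdname tidy.phase1_result
#' @export
glance.phase1_result <- function(x, ...) {
  tibble::tibble(case_id = x$case_id, pass = x$pass,
                 n_spheres_kept = n_spheres(x$spheres),
                 dice = x$contour_qc$dice, msd_mm = x$contour_qc$msd_mm,
                 gamma_pass_pct = if (is.null(x$gamma)) NA_real_
                                  else x$gamma$pass_rate_pct,
                 total_seconds = sum(x$timing$seconds))
}
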
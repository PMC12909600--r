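in_mask_doses <- function(dose, mask) {
  check_same_grid(dose$grid, mask$grid, "dose and structure")
  if (is_empty_mask(mask)) stop("structure '", mask$name, "' is empty")
  dose$dose_gy[mask$occupancy]
}

#' Cumulative dose-volume histogram
#'
#' Cumulative DVH of a structure: for each dose level, the fraction (and
#' absolute volume) of the structure receiving at least that dose. The curve
#' is monotone non-increasing and starts at 100% at 0 Gy.
#'
#' @param dose A [dose_grid()].
#' @param mask A non-empty [structure_mask()] on the same grid.
#' @param bin_gy Dose-axis bin width in Gy, default 0.05.
#' @return A tibble of class `dvh_curve` with columns `structure`,
#'   `dose_gy`, `volume_pct`, `volume_cc`.
#' @export
dvh_curve <- function(dose, mask, bin_gy = 0.05) {
  ds <- in_mask_doses(dose, mask)
  vv <- voxel_volume_cc(mask$grid)
  axis <- seq(0, max(ds) + bin_gy, by = bin_gy)
  n_ge <- length(ds) - findInterval(axis - 1e-12, sort(ds))
  out <- tibble::tibble(structure = mask$name, dose_gy = axis,
                        volume_pct = 100 * n_ge / length(ds),
                        volume_cc = n_ge * vv)
  class(out) <- c("dvh_curve", class(out))
  out
}

#' Dose at volume (DxCC / Dx%)
#'
#' The largest dose `d` such that the structure volume receiving at least
#' `d` is at least the requested volume, computed from the descending-sorted
#' voxel doses with partial-voxel linear interpolation at the cut (at 2 mm
#' spacing a voxel is 0.008 cc, so the 0.03 cc near-maximum involves about
#' four voxels). Ties are broken by a stable descending sort.
#'
#' @param dose A [dose_grid()].
#' @param mask A non-empty [structure_mask()] on the same grid.
#' @param volume_cc Requested absolute volume in cc, or
#' @param volume_pct requested relative volume in percent of the structure
#'   (exactly one of the two).
#' @return Dose in Gy.
#' @examples
#' # D0.03cc: dose_at_volume(dose, ptv, volume_cc = 0.03)
#' # D95%:    dose_at_volume(dose, ptv, volume_pct = 95)
#' @export
dose_at_volume <- function(dose, mask, volume_cc = NULL, volume_pct = NULL) {
  if (is.null(volume_cc) == is.null(volume_pct))
    stop("give exactly one of volume_cc or volume_pct")
  ds <- sort(in_mask_doses(dose, mask), decreasing = TRUE, method = "radix")
  vv <- voxel_volume_cc(mask$grid)
  n <- length(ds)
  if (!is.null(volume_pct)) {
    stopifnot(volume_pct >= 0, volume_pct <= 100)
    volume_cc <- volume_pct / 100 * n * vv
  }
  if (volume_cc > n * vv * (1 + 1e-9))
    stop("requested volume (", volume_cc, " cc) exceeds the structure volume (",
         n * vv, " cc)")
  f <- min(volume_cc / vv, n)
  if (f <= 1) return(ds[1L])
  k <- floor(f)
  frac <- f - k
  if (k >= n) return(ds[n])
  ds[k] + frac * (ds[k + 1L] - ds[k])
}

#' Volume at dose (VxGy)
#'
#' Fraction (percent) or absolute volume (cc) of the structure receiving at
#' least the threshold dose.
#'
#' @inheritParams dose_at_volume
#' @param threshold_gy Dose threshold in Gy.
#' @param mode `"pct"` for percent of the structure, `"cc"` for absolute cc.
#' @return Percent or cc.
#' @export
volume_at_dose <- function(dose, mask, threshold_gy, mode = c("pct", "cc")) {
  mode <- match.arg(mode)
  ds <- in_mask_doses(dose, mask)
  n_ge <- sum(ds >= threshold_gy)
  if (mode == "pct") 100 * n_ge / length(ds)
  else n_ge * voxel_volume_cc(mask$grid)
}

#' Mean structure dose
#' @inheritParams dose_at_volume
#' @return Mean dose in Gy over the structure's voxels.
#' @export
mean_dose <- function(dose, mask) mean(in_mask_doses(dose, mask))

#' RTOG conformity index
#'
#' Ratio of the prescription-isodose volume inside the body contour to the
#' target volume; 1.0 is perfectly conformal, values above 1 indicate dose
#' spill.
#'
#' @inheritParams dose_at_volume
#' @param target Non-empty target [structure_mask()].
#' @param rx_gy Prescription dose in Gy.
#' @param body Body [structure_mask()] bounding the isodose volume.
#' @return Conformity index (dimensionless).
#' @export
rtog_ci <- function(dose, target, rx_gy, body) {
  stopifnot(rx_gy > 0)
  if (is_empty_mask(target)) stop("conformity index of an empty target")
  v_iso <- volume_at_dose(dose, body, rx_gy, mode = "cc")
  v_iso / volume_cc(target)
}

#' Planning objective sets
#'
#' The standard lattice-SBRT objective set used by the planning template:
#' PTV_High `V12Gy >= 90%` and `D0.03cc <= 15 Gy`; PTV_Low `D95% >= 4 Gy`,
#' `D0.03cc <= 12 Gy` and `Dmean` in 3.50-5.50 Gy; normal-tissue ring
#' `D0.03cc <= 4 Gy`. `strict = TRUE` swaps in the clinical-acceptance
#' variant (`V4Gy >= 95%` for PTV_Low coverage and the tighter 5.0 Gy Dmean
#' upper bound).
#'
#' @param strict Use the stricter clinical-acceptance bounds.
#' @return Tibble of class `objective_set` with columns `structure`,
#'   `metric`, `comparator` (`ge`, `le`, `within`), `lo`, `hi`.
#' @export
sfrt_objectives <- function(strict = FALSE) {
  out <- tibble::tribble(
    ~structure, ~metric, ~comparator, ~lo, ~hi,
    "PTV_High", "V12Gy", "ge", 90, NA,
    "PTV_High", "D0.03cc", "le", NA, 15,
    "PTV_Low", if (strict) "V4Gy" else "D95%", "ge",
    if (strict) 95 else 4, NA,
    "PTV_Low", "D0.03cc", "le", NA, 12,
    "PTV_Low", "Dmean", "within", 3.5, if (strict) 5.0 else 5.5,
    "Ring", "D0.03cc", "le", NA, 4)
  class(out) <- c("objective_set", class(out))
  out
}

# Evaluate one metric string ("V12Gy", "D0.03cc", "D95%", "Dmean",
# "CI12Gy") on a dose/structure pair.
evaluate_metric <- function(dose, mask, metric, body = NULL) {
  if (metric == "Dmean") return(mean_dose(dose, mask))
  m <- regmatches(metric, regexec("^V([0-9.]+)Gy$", metric))[[1]]
  if (length(m)) return(volume_at_dose(dose, mask, as.numeric(m[2]), "pct"))
  m <- regmatches(metric, regexec("^D([0-9.]+)cc$", metric))[[1]]
  if (length(m)) return(dose_at_volume(dose, mask, volume_cc = as.numeric(m[2])))
  m <- regmatches(metric, regexec("^D([0-9.]+)%$", metric))[[1]]
  if (length(m)) return(dose_at_volume(dose, mask, volume_pct = as.numeric(m[2])))
  m <- regmatches(metric, regexec("^CI([0-9.]+)Gy$", metric))[[1]]
  if (length(m)) {
    if (is.null(body)) stop("conformity index requires a Body structure")
    return(rtog_ci(dose, mask, as.numeric(m[2]), body))
  }
  stop("unknown metric descriptor: ", metric)
}

#' Check a plan against an objective set
#'
#' Evaluates every objective on the given dose and structure set and reports
#' a machine-readable pass/fail table. A missing or empty referenced
#' structure is listed as failed with a reason rather than raising.
#'
#' @param dose A [dose_grid()].
#' @param structures A `structure_set` (or named list of masks).
#' @param objectives An `objective_set` from [sfrt_objectives()].
#' @return Tibble of class `metric_report` with columns `structure`,
#'   `metric`, `value`, `comparator`, `lo`, `hi`, `pass`, `note`; attribute
#'   `overall_pass` (also via [glance()]).
#' @export
check_objectives <- function(dose, structures, objectives = sfrt_objectives()) {
  rows <- lapply(seq_len(nrow(objectives)), function(i) {
    o <- objectives[i, ]
    mask <- structures[[o$structure]]
    if (is.null(mask) || is_empty_mask(mask)) {
      return(tibble::tibble(structure = o$structure, metric = o$metric,
                            value = NA_real_, comparator = o$comparator,
                            lo = o$lo, hi = o$hi, pass = FALSE,
                            note = "structure missing or empty"))
    }
    val <- evaluate_metric(dose, mask, o$metric, body = structures$Body)
    pass <- switch(o$comparator,
                   ge = val >= o$lo,
                   le = val <= o$hi,
                   within = val >= o$lo && val <= o$hi,
                   stop("unknown comparator ", o$comparator))
    tibble::tibble(structure = o$structure, metric = o$metric, value = val,
                   comparator = o$comparator, lo = o$lo, hi = o$hi,
                   pass = pass, note = "")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "overall_pass") <- all(out$pass)
  class(out) <- c("metric_report", class(out))
  out
}

#' Plan-vs-plan delta report
#'
#' Absolute differences between two plans for the standard Phase 1
#' evaluation metric families: PTV_High `D0.03cc`, `V12Gy`, `Dmean`, `V6Gy`
#' and the RTOG conformity index at 12 Gy; PTV_Low `D0.03cc`, `V4Gy`,
#' `Dmean`, `V12Gy`, `V8Gy`; normal-tissue ring `D0.03cc`. Symmetric in the
#' two plans.
#'
#' @param dose_a,dose_b [dose_grid()] objects on one common grid.
#' @param structures A `structure_set` containing `PTV_High`, `PTV_Low`,
#'   `Ring` and `Body`.
#' @return Tibble of class `delta_report` with columns `structure`,
#'   `metric`, `value_a`, `value_b`, `delta` (absolute).
#' @export
compare_plans <- function(dose_a, dose_b, structures) {
  check_same_grid(dose_a$grid, dose_b$grid, "plans")
  fam <- tibble::tribble(
    ~structure, ~metric,
    "PTV_High", "D0.03cc", "PTV_High", "V12Gy", "PTV_High", "Dmean",
    "PTV_High", "V6Gy", "PTV_High", "CI12Gy",
    "PTV_Low", "D0.03cc", "PTV_Low", "V4Gy", "PTV_Low", "Dmean",
    "PTV_Low", "V12Gy", "PTV_Low", "V8Gy",
    "Ring", "D0.03cc")
  va <- vb <- numeric(nrow(fam))
  for (i in seq_len(nrow(fam))) {
    mask <- structures[[fam$structure[i]]]
    va[i] <- evaluate_metric(dose_a, mask, fam$metric[i], structures$Body)
    vb[i] <- evaluate_metric(dose_b, mask, fam$metric[i], structures$Body)
  }
  out <- tibble::tibble(structure = fam$structure, metric = fam$metric,
                        value_a = va, value_b = vb, delta = abs(va - vb))
  class(out) <- c("delta_report", class(out))
  out
}
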
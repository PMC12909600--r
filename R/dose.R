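#' Scalar dose grid
#'
#' Absorbed dose in Gy on a [voxel_grid()], for a single phase, a single
#' fraction, or an accumulated total.
#'
#' @param grid A [voxel_grid()].
#' @param dose_gy Numeric array of non-negative doses, `dim == grid$dims`.
#' @param phase_label One of `"phase1"`, `"phase2_fraction"`, `"total"`.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(grid, dose_gy,
                      phase_label = c("phase1", "phase2_fraction", "total")) {
  phase_label <- match.arg(phase_label)
  dose_gy <- as.numeric(dose_gy)
  dim(dose_gy) <- grid$dims
  if (any(dose_gy < 0)) stop("dose must be non-negative everywhere")
  structure(list(grid = grid, dose_gy = dose_gy, phase_label = phase_label),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> [", x$phase_label, "] max ",
      format(max(x$dose_gy), digits = 4), " Gy on ",
      paste(x$grid$dims, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Accumulate dose grids voxelwise
#'
#' Sums a list of dose grids defined on one common grid, e.g. Phase 1 plus
#' four Phase 2 fractions. Accumulation is plain voxelwise addition, so it is
#' order-independent.
#'
#' @param doses List of [dose_grid()] objects on identical grids.
#' @return A [dose_grid()] labelled `"total"`.
#' @export
accumulate_dose <- function(doses) {
  stopifnot(length(doses) >= 1L)
  g <- doses[[1L]]$grid
  total <- array(0, dim = g$dims)
  for (d in doses) {
    check_same_grid(g, d$grid, "dose grids")
    total <- total + d$dose_gy
  }
  dose_grid(g, total, "total")
}
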
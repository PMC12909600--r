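#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cumulative DVH
#'
#' @param object A `dvh_curve` (or several row-bound curves).
#' @param ... Unused.
#' @return A ggplot of relative cumulative volume against dose.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy,
                                       y = .data$volume_pct,
                                       colour = .data$structure)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cumulative DVHs of a Phase 1 plan
#'
#' @param result A passing `phase1_result`.
#' @param structures Structure names to include.
#' @return A ggplot DVH.
#' @export
plot_dvh <- function(result, structures = c("PTV_High", "PTV_Low", "Ring")) {
  if (is.null(result$dose)) stop("result carries no dose (failed case)")
  curves <- dplyr::bind_rows(lapply(structures, function(nm)
    dvh_curve(result$dose, result$structures[[nm]])))
  class(curves) <- c("dvh_curve", class(curves))
  autoplot(curves)
}

#' Histogram of gamma values
#'
#' @param object A `gamma_result`.
#' @param ... Unused.
#' @return A ggplot histogram of per-voxel gamma with the pass line at 1.
#' @export
autoplot.gamma_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$gamma)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = expression(gamma), y = "Voxels") +
    ggplot2::theme_minimal()
}
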
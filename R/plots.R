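#' Plot CVH and LVH curves
#'
#' `autoplot()` methods render the cumulative curves the way DVHs are
#' usually drawn: level (as a percent) on the x axis, relative volume (CVH,
#' %) or absolute volume (LVH, cm^3) on the y axis.
#'
#' @param object A `"cvh"`, `"lvh"`, `iris_opt` or `iris_cohort` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cvh <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = 100 * .data$level, y = .data$volume_pct)
  ) +
    ggplot2::geom_step(direction = "vh", colour = "#2166ac") +
    ggplot2::labs(
      x = "coverage possibility (%)", y = "volume (% of structure)",
      title = "Coverage-volume histogram"
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100))
}

#' @rdname autoplot.cvh
#' @export
autoplot.lvh <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = 100 * .data$level, y = .data$volume_cm3)
  ) +
    ggplot2::geom_step(direction = "vh", colour = "#b2182b") +
    ggplot2::labs(
      x = "leakage possibility (%)", y = expression(volume ~ (cm^3)),
      title = "Leakage-volume histogram"
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 100))
}

#' @rdname autoplot.cvh
#' @export
autoplot.iris_opt <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::select(dplyr::all_of(c(
      "diameter", "c95_ctv", "c95_ptv", "mean_leakage", "feasible"
    ))) |>
    tidyr::pivot_longer(c("c95_ctv", "c95_ptv"),
                        names_to = "structure", values_to = "c95")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$diameter)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$c95,
                                    colour = .data$structure)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$c95, colour = .data$structure,
                                     shape = .data$feasible)) +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$mean_leakage),
                       linetype = "dashed", colour = "#b2182b") +
    ggplot2::geom_vline(xintercept = object$selected_diameter,
                        linetype = "dotted") +
    ggplot2::scale_y_continuous(
      "C95 (%)",
      sec.axis = ggplot2::sec_axis(~ . / 100, name = "mean leakage")
    ) +
    ggplot2::labs(x = "aperture diameter (mm)",
                  title = "Candidate apertures: coverage vs leakage")
}

#' @rdname autoplot.cvh
#' @export
autoplot.iris_cohort <- function(object, ...) {
  r <- object$results[!is.na(object$results$selected_diameter), ,
                      drop = FALSE]
  ggplot2::ggplot(
    r,
    ggplot2::aes(x = .data$phi_over_amin, y = .data$leak_cov_ratio,
                 colour = .data$threshold)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(
      x = expression(Phi / A[min]), y = "leakage / coverage ratio",
      colour = "coverage\nthreshold",
      title = "Aperture-to-short-axis ratio vs normal-tissue leakage"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
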
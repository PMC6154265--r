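#' Plot a simulation time course
#'
#' Faceted time series of the key outputs: inflammatory status, total
#' cross-sectional agonist, grown and loaded inner radii, and mean
#' outer-layer volume fractions.
#'
#' @param object An `airway_sim` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.airway_sim <- function(object, ...) {
  s <- object$series
  long <- tidyr::pivot_longer(
    s[, c("t", "mu", "k_total", "xi1", "r1_loaded",
          "phi_c_mean", "phi_p_mean", "phi_e_mean")],
    -"t", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL,
                  title = "Airway remodelling time course") +
    ggplot2::theme_minimal()
}

#' Plot a pressure-radius curve
#'
#' @param object A `pr_curve` tibble from [pressure_radius_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$transmural_pressure_kPa,
                               y = .data$inner_radius_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "transmural pressure (kPa)",
                  y = "inner radius (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a two-parameter sweep surface
#'
#' Tile plot of a sweep outcome over the two swept parameters; closed
#' (discarded) runs appear as missing tiles.
#'
#' @param object An `airway_sweep` from [parameter_sweep()].
#' @param metric Column to plot (default `remodelled_radius_mm`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.airway_sweep <- function(object, metric = "remodelled_radius_mm",
                                  ...) {
  axes <- attr(object, "axes")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data[[axes[1]]]),
                               y = factor(.data[[axes[2]]]),
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = axes[1], y = axes[2], fill = metric) +
    ggplot2::theme_minimal()
}

#' Plot a passive fit against its data
#'
#' @param object A `pr_fit` from [fit_passive_params()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_fit <- function(object, ...) {
  dat <- object$data
  fitted <- tibble::tibble(
    transmural_pressure_kPa = dat$transmural_pressure_kPa,
    inner_radius_mm = object$fitted
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$transmural_pressure_kPa,
                                    y = .data$inner_radius_mm)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(data = fitted, colour = "firebrick") +
    ggplot2::labs(x = "transmural pressure (kPa)",
                  y = "inner radius (mm)",
                  title = sprintf("Passive fit, R² = %.4f",
                                  object$r.squared)) +
    ggplot2::theme_minimal()
}
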
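# ggplot2 displays for the main result types.

#' Plot the excess-CO2 curve across sediment accumulation rates
#'
#' Total excess CO2 (solid line) and per-process contributions against SAR,
#' optionally with the horizontal band of excess CO2 implied by measured
#' air-water fluxes.
#'
#' @param curve A tibble from [excess_co2_curve()].
#' @param flux_band Optional numeric length-2: excess-CO2 band, umol kg-1.
#' @return A ggplot object.
#' @export
plot_excess_curve <- function(curve, flux_band = NULL) {
  long <- curve |>
    dplyr::select(
      "sar", "excess_ic", "excess_oc", "excess_crs", "excess_fe"
    ) |>
    tidyr::pivot_longer(-"sar", names_to = "process", values_to = "excess") |>
    dplyr::mutate(process = sub("^excess_", "", .data$process))
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$sar)) +
    ggplot2::geom_line(
      data = long,
      ggplot2::aes(y = .data$excess, colour = .data$process),
      linetype = "dashed"
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$excess_co2),
      linewidth = 1
    ) +
    ggplot2::labs(
      x = expression(paste("Sediment accumulation (g ", m^-2, " ", yr^-1, ")")),
      y = expression(paste("Excess ", CO[2], " (", mu, "mol ", kg^-1, ")")),
      colour = "Process"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(flux_band)) {
    p <- p + ggplot2::geom_hline(
      yintercept = flux_band, linetype = "dotted", colour = "grey40"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted pore-water profile
#'
#' Measured concentrations, the fitted model curve, and the fitted zone
#' structure (shaded by net production or consumption), depth increasing
#' downward.
#'
#' @param object A `zone_fit` from [fit_production()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zone_fit <- function(object, ...) {
  zones <- dplyr::mutate(
    object$zones,
    kind = ifelse(.data$rate >= 0, "production", "consumption")
  )
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = zones,
      ggplot2::aes(
        ymin = .data$top, ymax = .data$bottom,
        xmin = -Inf, xmax = Inf, fill = .data$kind
      ),
      alpha = 0.15
    ) +
    ggplot2::geom_path(
      data = object$grid,
      ggplot2::aes(x = .data$conc, y = .data$depth)
    ) +
    ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(x = .data$conc_umol_l, y = .data$depth_cm)
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = expression(paste("Concentration (", mu, "mol ", L^-1, ")")),
      y = "Depth (cm)", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Keeling fit
#'
#' delta against inverse concentration with the fitted line extended to the
#' intercept (the added-source endmember).
#'
#' @param object A `keeling_fit` from [keeling_intercept()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.keeling_fit <- function(object, ...) {
  d <- dplyr::mutate(object$data, inv_conc = 1 / .data$conc)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$inv_conc, y = .data$delta)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "steelblue"
    ) +
    ggplot2::expand_limits(x = 0) +
    ggplot2::labs(
      x = expression(paste("1 / [DIC] (kg ", mu, mol^-1, ")")),
      y = expression(paste(delta^13, "C (‰)"))
    ) +
    ggplot2::theme_minimal()
}
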
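# Air-water CO2 flux <-> steady-state excess-CO2 conversions.

#' Gas-exchange configuration
#'
#' @param k Gas transfer (piston) velocity, cm hr-1. The annual site average
#'   is 11.7 cm hr-1.
#' @param rho Water density, kg m-3. Default 1000; seawater density can be
#'   selected instead.
#' @return A list of class `gasex_config`.
#' @export
gasex_config <- function(k = 11.7, rho = 1000) {
  if (k <= 0) stop("gas transfer velocity must be positive", call. = FALSE)
  if (rho < 900 || rho > 1050) {
    stop("density outside plausible range [900, 1050] kg m-3", call. = FALSE)
  }
  structure(list(k = k, rho = rho), class = "gasex_config")
}

#' Convert an air-water CO2 flux to a steady-state excess concentration
#'
#' At steady state the air-water flux F = k * dCO2, so the dissolved-CO2
#' disequilibrium that sustains a measured flux is
#' `excess = F / (k * rho)` with k converted to m hr-1. The annual-average
#' emission of 700 umol m-2 hr-1 at k = 11.7 cm hr-1 corresponds to an
#' excess of 6.0 umol kg-1.
#'
#' @param flux Air-water CO2 flux, umol m-2 hr-1 (positive = evasion).
#' @param config A [gasex_config()].
#' @return Excess CO2, umol kg-1.
#' @seealso [excess_to_flux()] for the inverse.
#' @export
#' @examples
#' flux_to_excess(c(700, 610))
flux_to_excess <- function(flux, config = gasex_config()) {
  flux / (config$k / 100 * config$rho)
}

#' @rdname flux_to_excess
#' @param excess Excess CO2, umol kg-1.
#' @export
excess_to_flux <- function(excess, config = gasex_config()) {
  excess * (config$k / 100 * config$rho)
}

#' Annualize an hourly areal flux
#'
#' Converts umol m-2 hr-1 to mol m-2 yr-1 using an 8760-hour year:
#' 700 umol m-2 hr-1 is 6.1 mol m-2 yr-1.
#'
#' @param flux Flux, umol m-2 hr-1.
#' @return Flux, mol m-2 yr-1.
#' @export
#' @examples
#' hourly_to_annual(700)
hourly_to_annual <- function(flux) {
  flux * 8760 * 1e-6
}
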
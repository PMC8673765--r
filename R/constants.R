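# Seawater CO2-system equilibrium constants, total pH scale, mol kg-sw^-1.
# Default set: Lueker et al. (2000) K1/K2, Dickson (1990) KB, Weiss (1974) K0,
# Millero (1995) KW, Uppstrom (1974) total boron.

#' Equilibrium constants for the seawater CO2 system
#'
#' Evaluates the dissociation and solubility constants needed to speciate the
#' carbonate system from total alkalinity and DIC, on the total pH scale.
#' The `"lueker"` set combines the Lueker et al. carbonic-acid constants with
#' the Dickson boric-acid constant, the Weiss CO2 solubility, the Millero
#' water dissociation constant, and Uppstrom's boron-to-salinity ratio. This
#' is the conventional default of the widely used carbonate-chemistry
#' packages and the only set currently registered.
#'
#' @param salinity Practical salinity (dimensionless).
#' @param temperature Temperature in degrees Celsius.
#' @param set Constant-set identifier; currently only `"lueker"`.
#'
#' @return A named list with elements `k0` (mol kg-1 atm-1), `k1`, `k2`, `kb`,
#'   `kw` (mol kg-1 scale as appropriate) and `tb` (total boron, mol kg-1).
#' @export
#' @examples
#' co2_constants(35, 25)
co2_constants <- function(salinity, temperature, set = "lueker") {
  set <- match.arg(set, c("lueker"))
  stopifnot(is.finite(salinity), is.finite(temperature))
  tk <- temperature + 273.15
  s <- salinity
  sqs <- sqrt(s)
  lnt <- log(tk)

  # Weiss (1974) CO2 solubility, mol kg-1 atm-1
  ln_k0 <- 93.4517 * (100 / tk) - 60.2409 + 23.3585 * log(tk / 100) +
    s * (0.023517 - 0.023656 * (tk / 100) + 0.0047036 * (tk / 100)^2)

  # Lueker et al. (2000), total scale
  pk1 <- 3633.86 / tk - 61.2172 + 9.67770 * lnt - 0.011555 * s + 0.0001152 * s^2
  pk2 <- 471.78 / tk + 25.9290 - 3.16967 * lnt - 0.01781 * s + 0.0001122 * s^2

  # Dickson (1990) boric acid, total scale
  ln_kb <- (-8966.90 - 2890.53 * sqs - 77.942 * s + 1.728 * s^1.5 -
    0.0996 * s^2) / tk +
    148.0248 + 137.1942 * sqs + 1.62142 * s +
    (-24.4344 - 25.085 * sqs - 0.2474 * s) * lnt +
    0.053105 * sqs * tk

  # Millero (1995) water dissociation, total scale
  ln_kw <- 148.96502 - 13847.26 / tk - 23.6521 * lnt +
    (118.67 / tk - 5.977 + 1.0495 * lnt) * sqs - 0.01615 * s

  list(
    k0 = exp(ln_k0),
    k1 = 10^(-pk1),
    k2 = 10^(-pk2),
    kb = exp(ln_kb),
    kw = exp(ln_kw),
    tb = 0.0004157 * s / 35,  # Uppstrom (1974)
    set = set
  )
}
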
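# Carbonate-system speciation from (TA, DIC, S, T) and the buffer factors
# used to translate alkalinity/DIC anomalies into dissolved-CO2 anomalies.

#' Define a water-column state
#'
#' Bundles the measured water-column carbonate-system variables into a
#' validated one-row tibble. Total alkalinity and DIC are in umol kg-1;
#' pressure is fixed at the surface (no pressure correction is applied, the
#' site is ~1 m deep).
#'
#' @param ta Total alkalinity, umol kg-1.
#' @param dic Dissolved inorganic carbon, umol kg-1.
#' @param salinity Practical salinity in [0, 45].
#' @param temperature Temperature, degrees Celsius, in [-2, 40].
#' @param pressure Pressure, dbar (recorded but unused; default 0).
#'
#' @return A one-row tibble of class `water_state` with columns `ta`, `dic`,
#'   `salinity`, `temperature`, `pressure`.
#' @export
#' @examples
#' water_state(2596, 2295, 38, 26)
water_state <- function(ta, dic, salinity, temperature, pressure = 0) {
  stopifnot(
    length(ta) == 1, length(dic) == 1,
    is.finite(ta), is.finite(dic), is.finite(salinity), is.finite(temperature)
  )
  if (ta <= 0) stop("total alkalinity must be positive", call. = FALSE)
  if (dic < 0) stop("DIC must be non-negative", call. = FALSE)
  if (salinity < 0 || salinity > 45) {
    stop("salinity outside supported range [0, 45]", call. = FALSE)
  }
  if (temperature < -2 || temperature > 40) {
    stop("temperature outside supported range [-2, 40] degC", call. = FALSE)
  }
  out <- tibble::tibble(
    ta = ta, dic = dic, salinity = salinity,
    temperature = temperature, pressure = pressure
  )
  class(out) <- c("water_state", class(out))
  out
}

# Total alkalinity (mol kg-1) implied by [H+] and DIC under a constant set.
# TA = HCO3 + 2 CO3 + B(OH)4 + OH - H (nutrient terms excluded by default).
ta_from_h <- function(h, dic, k) {
  den <- h * h + k$k1 * h + k$k1 * k$k2
  hco3 <- dic * k$k1 * h / den
  co3 <- dic * k$k1 * k$k2 / den
  boh4 <- k$tb * k$kb / (k$kb + h)
  oh <- k$kw / h
  hco3 + 2 * co3 + boh4 + oh - h
}

#' Solve the carbonate system from total alkalinity and DIC
#'
#' Finds the total-scale pH at which the alkalinity computed from DIC and the
#' acid-base equilibria matches the supplied total alkalinity, then returns
#' the full speciation. The root is found by monotone bisection on pH over
#' [2, 12]: the alkalinity residual is strictly decreasing in [H+], so
#' bisection converges unconditionally; iteration continues until the
#' bracketing interval in [H+] is below 1e-12 relative width.
#'
#' @param state A `water_state` (or any one-row data frame with columns
#'   `ta`, `dic`, `salinity`, `temperature`).
#' @param constants Constant-set identifier passed to [co2_constants()].
#'
#' @return A one-row tibble: `ph` (total scale), `co2_aq`, `hco3`, `co3`,
#'   `boh4`, `oh`, `h` (umol kg-1 except `ph`), and `pco2` (uatm).
#' @export
#' @examples
#' solve_speciation(water_state(2596, 2295, 38, 26))
solve_speciation <- function(state, constants = "lueker") {
  st <- as.list(state[1, ])
  k <- co2_constants(st$salinity, st$temperature, constants)
  ta <- st$ta * 1e-6
  dic <- st$dic * 1e-6

  f <- function(ph) ta_from_h(10^(-ph), dic, k) - ta
  lo <- 2
  hi <- 12
  flo <- f(lo)
  fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    stop(
      sprintf(
        "no pH root in [2, 12] for TA = %.6g, DIC = %.6g umol kg-1",
        st$ta, st$dic
      ),
      call. = FALSE
    )
  }
  # f(pH) is increasing (TA(pH) rises as H falls); bisect until the [H+]
  # bracket is below 1e-12 relative width.
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
    h_lo <- 10^(-hi)
    h_hi <- 10^(-lo)
    if ((h_hi - h_lo) <= 1e-12 * h_lo) break
  }
  if (i >= 200) {
    stop(
      sprintf(
        "pH bisection did not converge for TA = %.6g, DIC = %.6g umol kg-1",
        st$ta, st$dic
      ),
      call. = FALSE
    )
  }
  ph <- (lo + hi) / 2
  h <- 10^(-ph)
  den <- h * h + k$k1 * h + k$k1 * k$k2
  co2 <- dic * h * h / den
  hco3 <- dic * k$k1 * h / den
  co3 <- dic * k$k1 * k$k2 / den
  tibble::tibble(
    ph = ph,
    co2_aq = co2 * 1e6,
    hco3 = hco3 * 1e6,
    co3 = co3 * 1e6,
    boh4 = k$tb * k$kb / (k$kb + h) * 1e6,
    oh = k$kw / h * 1e6,
    h = h * 1e6,
    pco2 = co2 / k$k0 * 1e6
  )
}

#' Buffer factors for dissolved CO2
#'
#' Computes the alkalinity and DIC buffer factors gamma_TA and gamma_DIC of
#' the Egleston-Sabine-Morel framework, defined so that for infinitesimal
#' perturbations
#' \deqn{d[CO2]/[CO2] = dDIC / \gamma_{DIC} + dTA / \gamma_{TA}.}
#' With `AC = [HCO3] + 2[CO3]` and
#' `S = [HCO3] + 4[CO3] + H*B(OH)4/(KB + H) + [H] + [OH]`, the closed forms
#' are `gamma_DIC = DIC - AC^2/S` and `gamma_TA = (AC^2 - DIC*S)/AC`. In the
#' open-ocean and lagoon range (TA > DIC > 0), gamma_DIC > 0 and
#' gamma_TA < 0: dissolved CO2 rises with DIC and falls with alkalinity.
#'
#' @inheritParams solve_speciation
#' @return A one-row tibble with `gamma_dic` and `gamma_ta`, umol kg-1.
#' @export
#' @examples
#' buffer_factors(water_state(2596, 2295, 38, 26))
buffer_factors <- function(state, constants = "lueker") {
  st <- as.list(state[1, ])
  sp <- solve_speciation(state, constants)
  k <- co2_constants(st$salinity, st$temperature, constants)
  h <- sp$h * 1e-6
  hco3 <- sp$hco3 * 1e-6
  co3 <- sp$co3 * 1e-6
  boh4 <- k$tb * k$kb / (k$kb + h)
  oh <- k$kw / h
  dic <- st$dic * 1e-6

  ac <- hco3 + 2 * co3
  s <- hco3 + 4 * co3 + h * boh4 / (k$kb + h) + h + oh
  if (abs(s) < 1e-15 || abs(ac) < 1e-15) {
    stop("degenerate state: buffer-factor denominator vanishes", call. = FALSE)
  }
  gamma_dic <- dic - ac^2 / s
  gamma_ta <- (ac^2 - dic * s) / ac
  tibble::tibble(gamma_dic = gamma_dic * 1e6, gamma_ta = gamma_ta * 1e6)
}

#' Excess CO2 from a TA/DIC perturbation
#'
#' Returns the change in dissolved CO2 (CO2_after - CO2_before, umol kg-1)
#' produced by adding `dta` and `ddic` to the water column. In `"linearized"`
#' mode the buffer-factor differential is applied directly,
#' `dCO2 = [CO2] * (ddic/gamma_DIC + dta/gamma_TA)`, which is exactly linear
#' in the perturbation; in `"full_resolve"` mode the carbonate system is
#' re-solved at (TA + dta, DIC + ddic) and the CO2 concentrations differenced.
#'
#' @inheritParams solve_speciation
#' @param dta,ddic Perturbations to TA and DIC, umol kg-1.
#' @param mode `"linearized"` or `"full_resolve"`.
#' @return Excess CO2, umol kg-1 (scalar).
#' @export
#' @examples
#' st <- water_state(2596, 2295, 38, 26)
#' perturb_state(st, dta = -2, ddic = -1) # CaCO3 precipitation releases CO2
perturb_state <- function(state, dta, ddic,
                          mode = c("linearized", "full_resolve"),
                          constants = "lueker") {
  mode <- match.arg(mode)
  sp <- solve_speciation(state, constants)
  if (mode == "linearized") {
    bf <- buffer_factors(state, constants)
    sp$co2_aq * (ddic / bf$gamma_dic + dta / bf$gamma_ta)
  } else {
    st <- as.list(state[1, ])
    state2 <- water_state(
      st$ta + dta, st$dic + ddic, st$salinity, st$temperature
    )
    solve_speciation(state2, constants)$co2_aq - sp$co2_aq
  }
}
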
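# Independent oracles, coded separately from the package implementation.

# Carbonate-system oracle: same constant set, independent arithmetic and an
# independent root finder (stats::uniroot on pH instead of the package's
# hand-rolled bisection). Returns speciation in umol kg-1.
oracle_speciation <- function(ta, dic, salinity, temperature) {
  k <- co2_constants(salinity, temperature)
  ta <- ta * 1e-6
  dic <- dic * 1e-6
  alk_resid <- function(ph) {
    h <- 10^(-ph)
    gamma <- h^2 + k$k1 * h + k$k1 * k$k2
    carb_alk <- dic * (k$k1 * h + 2 * k$k1 * k$k2) / gamma
    carb_alk + k$tb / (1 + h / k$kb) + k$kw / h - h - ta
  }
  ph <- stats::uniroot(alk_resid, c(2, 12), tol = 1e-14)$root
  h <- 10^(-ph)
  gamma <- h^2 + k$k1 * h + k$k1 * k$k2
  list(
    ph = ph,
    co2_aq = dic * h^2 / gamma * 1e6,
    hco3 = dic * k$k1 * h / gamma * 1e6,
    co3 = dic * k$k1 * k$k2 / gamma * 1e6
  )
}

# Central finite-difference buffer factors: re-solve the speciation at
# DIC +/- 0.1 and TA +/- 0.1 umol kg-1 and difference ln[CO2].
oracle_buffer_fd <- function(ta, dic, salinity, temperature, step = 0.1) {
  co2_at <- function(ta_i, dic_i) {
    oracle_speciation(ta_i, dic_i, salinity, temperature)$co2_aq
  }
  dlnco2_ddic <- (log(co2_at(ta, dic + step)) - log(co2_at(ta, dic - step))) /
    (2 * step)
  dlnco2_dta <- (log(co2_at(ta + step, dic)) - log(co2_at(ta - step, dic))) /
    (2 * step)
  list(gamma_dic = 1 / dlnco2_ddic, gamma_ta = 1 / dlnco2_dta)
}

# Random seawater-range states for property tests.
random_states <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      ta = stats::runif(n, 2300, 2700),
      dic = stats::runif(n, 1900, 2400),
      salinity = stats::runif(n, 30, 40),
      temperature = stats::runif(n, 15, 30)
    )
  })
}

# Analytic single-zone solution with constant diffusivity, zero bottom flux:
# C(z) = C0 + (R / 2D) * (2 L z - z^2).
parabola_solution <- function(z, c0, rate, d, l) {
  c0 + rate / (2 * d) * (2 * l * z - z^2)
}
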
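# Synthetic inputs with the statistical structure the analysis assumes:
# zone-structured pore-water profiles, paired inflow/outflow incubations,
# two-endmember isotope mixing, and 30-min air-water flux series.
#
# A single top-level seed fans out to independent per-generator streams by
# offsetting the seed, so the generators can be used together or alone.

fan_seed <- function(seed, offset) {
  if (is.null(seed)) NULL else (as.integer(seed) + offset) %% .Machine$integer.max
}

with_stream <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Synthetic pore-water profile with known generating truth
#'
#' Generates a depth-resolved pore-water concentration profile by solving
#' the steady-state diffusion-reaction model for a prescribed zone structure
#' and adding i.i.d. Gaussian analytical noise, returning both the noisy
#' profile and the generating truth so inversion can be tested as parameter
#' recovery. The default zone structure mimics a vegetated carbonate
#' sediment: net DIC consumption above ~10 cm (carbonate reprecipitation and
#' sulfide oxidation), a production maximum at mid-depth, and weak
#' consumption at depth, giving the characteristic mid-column DIC maximum.
#' An optional d13C
#' column is generated by exact mass-balance mixing of the background pool
#' with an added source of signature `delta_source`, so a Keeling plot of
#' the noiseless values is exactly linear in 1/concentration.
#'
#' @param depths Sample depths, cm (default 5-cm resolution to 30 cm).
#' @param boundaries,rates Zone boundaries (cm, from 0) and net volumetric
#'   production per zone (umol L-1 hr-1).
#' @param params A [transport_params()].
#' @param top_bc Surface-water concentration, umol L-1.
#' @param bottom_flux Upward flux across the bottom boundary, umol m-2 hr-1.
#' @param noise_sd Gaussian noise SD on concentrations, umol L-1.
#' @param delta_background,delta_source Background and added-source d13C,
#'   permil; set `delta_source = NULL` to skip the isotope column.
#' @param delta_noise_sd Gaussian noise SD on d13C, permil.
#' @param h Grid spacing of the generating forward solve, cm.
#' @param seed Integer seed (byte-identical regeneration for a fixed seed).
#' @return A list: `profile` (tibble `depth_cm`, `conc_umol_l`
#'   [, `d13c_permil`]), `truth` (zone tibble plus `flux_top`,
#'   `flux_bottom`, `top_bc`).
#' @export
#' @examples
#' synth_porewater(seed = 1)$profile
synth_porewater <- function(depths = seq(2.5, 30, by = 5),
                            boundaries = c(0, 10, 20, 30),
                            rates = c(-0.004, 0.008, -0.002),
                            params = transport_params(
                              d_mol = 0.04, d_bio = 3, bio_depth = 15
                            ),
                            top_bc = 2295,
                            bottom_flux = 0,
                            noise_sd = 0,
                            delta_background = -3.9,
                            delta_source = 0,
                            delta_noise_sd = 0,
                            h = 0.5,
                            seed = NULL) {
  sol <- forward_solve(params, boundaries, rates, top_bc, bottom_flux, h)
  conc_true <- interp_solution(
    augment_faces(sol, params, top_bc, bottom_flux, h), depths
  )
  flux_top <- sum(h * params$porosity * sol$rate) * FLUX_UNIT + bottom_flux

  noise <- with_stream(
    fan_seed(seed, 101L),
    stats::rnorm(length(depths), 0, noise_sd)
  )
  profile <- tibble::tibble(
    depth_cm = depths,
    conc_umol_l = pmax(conc_true + noise, 0)
  )
  if (!is.null(delta_source)) {
    # mass balance: background pool C0 at delta_background, excess added at
    # delta_source -> delta is linear in 1/C with intercept delta_source
    d_true <- (top_bc * delta_background +
      (conc_true - top_bc) * delta_source) / conc_true
    d_noise <- with_stream(
      fan_seed(seed, 211L),
      stats::rnorm(length(depths), 0, delta_noise_sd)
    )
    profile$d13c_permil <- d_true + d_noise
  }
  list(
    profile = profile,
    truth = list(
      zones = tibble::tibble(
        top = boundaries[-length(boundaries)],
        bottom = boundaries[-1],
        rate = rates
      ),
      flux_top = flux_top,
      flux_bottom = bottom_flux,
      top_bc = top_bc,
      conc_true = conc_true
    )
  )
}

#' Synthetic continuous-flow incubation table
#'
#' Emulates the incubation design: cores per site/treatment, each sampled
#' five times over 48 hours, with outflow concentrations generated from the
#' true flux (`c_out = c_in + flux * area / flow + noise`). Default true
#' fluxes mirror the observed sign structure for net N2 exchange: only
#' high-density cores with living biomass net denitrifying, all other
#' treatments weakly N2-fixing, with analytical noise large enough that the
#' all-core mean is statistically indistinguishable from zero.
#'
#' @param true_fluxes Tibble with columns `site`, `treatment`,
#'   `flux` (umol m-2 hr-1); defaults to the N2-like sign structure.
#' @param n_rep Cores per site/treatment (default 4, quadruplicate).
#' @param n_times Sampling occasions per core over 48 h (default 5).
#' @param c_in Inflow concentration, umol L-1.
#' @param flow_ml_min Flow rate, mL min-1 (default 1.5).
#' @param diameter_cm Core inner diameter, cm (default 6.4).
#' @param noise_sd Analytical noise SD on the outflow concentration,
#'   umol L-1.
#' @param analyte Analyte label carried through.
#' @param seed Integer seed.
#' @return A tibble with one row per core x occasion: `core_id`, `site`,
#'   `treatment`, `time_h`, `c_in`, `c_out`, `flow_ml_min`, `diameter_cm`,
#'   `analyte`, `true_flux`.
#' @export
synth_incubation <- function(true_fluxes = NULL,
                             n_rep = 4, n_times = 5,
                             c_in = 420, flow_ml_min = 1.5,
                             diameter_cm = 6.4, noise_sd = 0.8,
                             analyte = "N2", seed = NULL) {
  if (is.null(true_fluxes)) {
    true_fluxes <- tibble::tibble(
      site = c("B", "HD", "HD", "LD", "LD"),
      treatment = c(
        "without_biomass", "with_biomass", "without_biomass",
        "with_biomass", "without_biomass"
      ),
      flux = c(-10, 25, -12, -8, -10)
    )
  }
  stopifnot(n_rep >= 1, n_times >= 1)
  area <- pi * (diameter_cm / 200)^2 # m2
  flow_l_hr <- flow_ml_min * 1e-3 * 60

  design <- tidyr::crossing(
    true_fluxes,
    rep = seq_len(n_rep),
    time_h = seq(0, 48, length.out = n_times + 1)[-1]
  ) |>
    dplyr::mutate(
      core_id = paste(.data$site, substr(.data$treatment, 1, 4), .data$rep,
        sep = "_"
      )
    )
  noise <- with_stream(
    fan_seed(seed, 307L),
    stats::rnorm(nrow(design), 0, noise_sd)
  )
  design |>
    dplyr::transmute(
      core_id = .data$core_id,
      site = .data$site,
      treatment = .data$treatment,
      time_h = .data$time_h,
      c_in = c_in,
      c_out = c_in + .data$flux * area / flow_l_hr + noise,
      flow_ml_min = flow_ml_min,
      diameter_cm = diameter_cm,
      analyte = analyte,
      true_flux = .data$flux
    )
}

#' Synthetic 30-minute air-water CO2 flux series
#'
#' Mean flux plus a seasonally modulated diel harmonic plus Gaussian noise,
#' at 30-minute resolution: emulating eddy-covariance CO2 flux series whose
#' afternoon emissions exceed night-time emissions in the warm seasons but
#' show no diel cycle in fall.
#'
#' @param n_days Length of the series, days.
#' @param mean_flux Mean flux, umol m-2 hr-1 (default 700, the annual
#'   average emission).
#' @param sd_flux Gaussian noise SD (default 660).
#' @param diel_amplitude Amplitude of the diel harmonic, umol m-2 hr-1
#'   (0 = no day-night difference; positive peaks mid-afternoon).
#' @param start_day Day-of-year of the first record (cosmetic).
#' @param seed Integer seed.
#' @return A tibble: `time_h` (hours from start), `day`, `hour_of_day`,
#'   `flux` (umol m-2 hr-1).
#' @export
synth_flux_series <- function(n_days = 30, mean_flux = 700, sd_flux = 660,
                              diel_amplitude = 0, start_day = 1,
                              seed = NULL) {
  stopifnot(n_days >= 1)
  time_h <- seq(0, n_days * 24 - 0.5, by = 0.5)
  hour <- time_h %% 24
  # peak at 15:00 local
  harmonic <- diel_amplitude * cos(2 * pi * (hour - 15) / 24)
  noise <- with_stream(
    fan_seed(seed, 419L),
    stats::rnorm(length(time_h), 0, sd_flux)
  )
  tibble::tibble(
    time_h = time_h,
    day = start_day + floor(time_h / 24),
    hour_of_day = hour,
    flux = mean_flux + harmonic + noise
  )
}

#' Daily means of a 30-minute flux series
#'
#' @param series A tibble from [synth_flux_series()] (columns `day`, `flux`).
#' @return A tibble: `day`, `n`, `mean_flux`.
#' @export
flux_daily_means <- function(series) {
  series |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      n = dplyr::n(), mean_flux = mean(.data$flux),
      .groups = "drop"
    )
}

#' Diel climatology of a 30-minute flux series
#'
#' Bins records by hour of day into fixed-width bins (default 2 h) and
#' averages, as used to display seasonal day-night structure.
#'
#' @param series A tibble with `hour_of_day` and `flux`.
#' @param bin_h Bin width, hours.
#' @return A tibble: `bin_start`, `bin_mid`, `n`, `mean_flux`, `sd_flux`.
#' @export
flux_diel_climatology <- function(series, bin_h = 2) {
  series |>
    dplyr::mutate(bin_start = floor(.data$hour_of_day / bin_h) * bin_h) |>
    dplyr::group_by(.data$bin_start) |>
    dplyr::summarise(
      bin_mid = .data$bin_start[1] + bin_h / 2,
      n = dplyr::n(),
      mean_flux = mean(.data$flux),
      sd_flux = stats::sd(.data$flux),
      .groups = "drop"
    )
}

#' Synthetic Keeling-plot samples from two-endmember mixing
#'
#' Draws mixed-pool samples along a concentration range under exact
#' two-endmember mass balance (background pool plus added source), with
#' optional Gaussian noise on delta, for testing the Keeling intercept's
#' recovery of the source signature.
#'
#' @param n Number of samples.
#' @param background_conc Background pool concentration, umol kg-1.
#' @param delta_background Background pool signature, permil.
#' @param delta_source Added-source signature, permil.
#' @param added_range Range of added concentrations, umol kg-1.
#' @param noise_sd Gaussian noise SD on delta, permil.
#' @param seed Integer seed.
#' @return A tibble: `conc`, `delta`, `added`.
#' @export
synth_keeling_samples <- function(n = 20, background_conc = 2295,
                                  delta_background = -3.9, delta_source = 0,
                                  added_range = c(200, 2500),
                                  noise_sd = 0, seed = NULL) {
  stopifnot(n >= 3)
  added <- seq(added_range[1], added_range[2], length.out = n)
  conc <- background_conc + added
  delta <- (background_conc * delta_background + added * delta_source) / conc
  noise <- with_stream(
    fan_seed(seed, 523L),
    stats::rnorm(n, 0, noise_sd)
  )
  tibble::tibble(conc = conc, delta = delta + noise, added = added)
}
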
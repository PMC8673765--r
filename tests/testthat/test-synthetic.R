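test_that("a noise-free synthetic profile is the forward solution exactly", {
  syn <- synth_porewater(noise_sd = 0, delta_noise_sd = 0)
  expect_equal(syn$profile$conc_umol_l, syn$truth$conc_true)
})

test_that("the vegetated-sediment default shows a mid-depth DIC maximum and heavy d13C", {
  syn <- synth_porewater(
    depths = seq(1.25, 30, by = 1.25), noise_sd = 0
  )
  prof <- syn$profile
  peak_depth <- prof$depth_cm[which.max(prof$conc_umol_l)]
  expect_gt(peak_depth, 10) # maximum below the consumption zone
  expect_lt(peak_depth, 30)
  # DIC added at depth carries the heavier (carbonate-dissolution) signature
  enriched <- prof$d13c_permil[prof$conc_umol_l > 2295]
  expect_true(all(enriched > -3.9))
  expect_gt(length(enriched), 0)
})

test_that("synthetic generation is reproducible for a fixed seed", {
  a <- synth_porewater(noise_sd = 1, delta_noise_sd = 0.2, seed = 12)
  b <- synth_porewater(noise_sd = 1, delta_noise_sd = 0.2, seed = 12)
  expect_identical(a$profile, b$profile)

  ia <- synth_incubation(seed = 12)
  ib <- synth_incubation(seed = 12)
  expect_identical(ia, ib)

  fa <- synth_flux_series(n_days = 3, seed = 12)
  fb <- synth_flux_series(n_days = 3, seed = 12)
  expect_identical(fa, fb)
})

test_that("noise-free incubations return their generating fluxes exactly", {
  inc <- synth_incubation(noise_sd = 0)
  fluxes <- core_flux(inc)
  expect_lt(max(abs(fluxes$flux - fluxes$true_flux)), 1e-9)
})

test_that("the incubation default reproduces the measured sign structure", {
  inc <- synth_incubation(seed = 31)
  groups <- replicate_summary(core_flux(inc), site, treatment)
  hd_bio <- groups[groups$site == "HD" & groups$treatment == "with_biomass", ]
  expect_gt(hd_bio$mean, 0) # only vegetated high-density cores denitrify
  others <- groups[!(groups$site == "HD" & groups$treatment == "with_biomass"), ]
  expect_true(all(others$mean < 0)) # everything else net N2-fixing
})

test_that("a constant flux series annualizes to the reported rate", {
  series <- synth_flux_series(
    n_days = 5, mean_flux = 700, sd_flux = 0, diel_amplitude = 0
  )
  daily <- flux_daily_means(series)
  expect_true(all(daily$mean_flux == 700))
  expect_equal(signif(hourly_to_annual(mean(series$flux)), 2), 6.1)
})

test_that("a flat diel spec shows no day-night difference most of the time", {
  p_vals <- vapply(1:100, function(s) {
    series <- synth_flux_series(
      n_days = 7, mean_flux = 610, sd_flux = 660,
      diel_amplitude = 0, seed = 2000 + s
    )
    day <- series$flux[series$hour_of_day >= 8 & series$hour_of_day < 20]
    night <- series$flux[series$hour_of_day < 8 | series$hour_of_day >= 20]
    suppressWarnings(stats::wilcox.test(day, night)$p.value)
  }, numeric(1))
  expect_gte(mean(p_vals > 0.05), 0.90)
})

test_that("a summer-like diel amplitude raises afternoon over night emissions", {
  series <- synth_flux_series(
    n_days = 10, mean_flux = 700, sd_flux = 0, diel_amplitude = 300
  )
  clim <- flux_diel_climatology(series, bin_h = 2)
  afternoon <- clim$mean_flux[clim$bin_start == 14]
  night <- clim$mean_flux[clim$bin_start == 2]
  expect_gt(afternoon, night)
})

test_that("the full synthetic pipeline runs end to end", {
  params <- transport_params(d_mol = 0.04, d_bio = 0, porosity = 0.7)
  syn_prof <- synth_porewater(
    depths = seq(1.25, 30, by = 1.25), boundaries = c(0, 15, 30),
    rates = c(-0.004, 0.006), params = params,
    noise_sd = 0.3, delta_noise_sd = 0.2, seed = 77
  )
  fit <- fit_production(
    syn_prof$profile, params,
    max_zones = 3, top_bc = 2295, bottom_flux = 0
  )
  expect_true(all(is.finite(fit$zones$rate)))
  expect_true(is.finite(sediment_water_flux(fit)))

  inc <- synth_incubation(seed = 77)
  summary <- replicate_summary(core_flux(inc), site, treatment)
  expect_true(all(is.finite(summary$mean)))

  keeling <- keeling_intercept(
    dplyr::transmute(
      syn_prof$profile,
      conc = conc_umol_l, delta = d13c_permil
    ),
    seed = 77
  )
  expect_true(is.finite(keeling$intercept))

  report <- run_budget_report()
  expect_equal(
    report$shares$share_ic + report$shares$share_oc +
      report$shares$share_redox,
    100
  )
  expect_true(all(is.finite(report$curve$excess_co2)))
})
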
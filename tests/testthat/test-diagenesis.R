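# Benchmark transport: molecular-only, constant porosity (see vignette for
# why the recovery experiment avoids the biodiffusive layer).
bench_params <- transport_params(d_mol = 0.04, d_bio = 0, porosity = 0.7)

test_that("molecular diffusivities match independently keyed literature values", {
  # Li & Gregory style 25 degC seawater values, keyed in cm2 hr-1
  expect_lt(abs(molecular_diffusivity("DIC", 25, 35) / 0.0404 - 1), 0.10)
  expect_lt(abs(molecular_diffusivity("H2S", 25, 35) / 0.0598 - 1), 0.10)

  # diffusivity rises with temperature
  for (solute in c("DIC", "H2S")) {
    expect_gt(
      molecular_diffusivity(solute, 30, 38),
      molecular_diffusivity(solute, 20, 38)
    )
  }

  # porosity = 1 applies no tortuosity correction
  free <- molecular_diffusivity("DIC", 26, 38)
  phi <- 0.7
  expect_equal(
    molecular_diffusivity("DIC", 26, 38, porosity = phi),
    free / (1 - log(phi^2))
  )
  expect_error(molecular_diffusivity("DIC", 25, 35, porosity = 0), "porosity")
})

test_that("without production or bottom flux the profile is the top concentration", {
  sol <- forward_solve(
    bench_params, c(0, 20),
    rates = 0, top_bc = 2295, bottom_flux = 0
  )
  expect_lt(max(abs(sol$conc - 2295)), 1e-9)
})

test_that("constant production reproduces the analytic parabola", {
  d <- 0.04
  l <- 10
  rate <- 0.01
  sol <- forward_solve(
    transport_params(d_mol = d, d_bio = 0, porosity = 0.7),
    c(0, l),
    rates = rate, top_bc = 2000, bottom_flux = 0, h = 0.1
  )
  # note phi cancels: C'' = -R/D for constant phi
  truth <- parabola_solution(sol$depth, 2000, rate, d, l)
  expect_lt(max(abs(sol$conc - truth) / truth), 1e-6)
})

test_that("the discretization conserves mass cell by cell", {
  params <- transport_params(d_mol = 0.04, d_bio = 2, bio_depth = 8,
    porosity = 0.6)
  h <- 0.5
  sol <- forward_solve(
    params, c(0, 10, 24),
    rates = c(-0.003, 0.008),
    top_bc = 2295, bottom_flux = 1.2, h = h
  )
  phi <- params$porosity
  d <- params$d_mol + ifelse(sol$depth <= params$bio_depth, params$d_bio, 0)
  pd <- phi * d
  n <- nrow(sol)
  # reconstruct upward face fluxes (conc-gradient units)
  t_int <- 2 * pd[-n] * pd[-1] / (pd[-n] + pd[-1]) / h
  g <- c(
    pd[1] / (h / 2) * (sol$conc[1] - 2295), # top face
    t_int * diff(sol$conc), # interior faces
    1.2 / 10 # bottom face (umol m-2 hr-1 / unit factor)
  )
  divergence <- diff(g)
  expect_lt(max(abs(divergence + h * phi * sol$rate)), 1e-9)
})

test_that("a zero-diffusivity column is rejected as singular", {
  expect_error(
    forward_solve(
      transport_params(d_mol = 0), c(0, 10),
      rates = 0.1, top_bc = 100
    ),
    "singular"
  )
})

test_that("profile validation catches malformed tables", {
  good <- tibble::tibble(depth_cm = 1:5, conc_umol_l = 5:1)
  expect_s3_class(porewater_profile(good), "tbl_df")
  expect_error(porewater_profile(good[1:3, ]), "at least 4")
  bad_depth <- good
  bad_depth$depth_cm <- c(1, 2, 2, 4, 5)
  expect_error(porewater_profile(bad_depth), "increasing")
  bad_conc <- good
  bad_conc$conc_umol_l[2] <- -1
  expect_error(porewater_profile(bad_conc), "non-negative")
})

test_that("a noiseless two-zone profile is recovered exactly", {
  truth_rates <- c(-0.004, 0.006)
  syn <- synth_porewater(
    depths = seq(1.25, 30, by = 1.25), boundaries = c(0, 15, 30),
    rates = truth_rates, params = bench_params,
    top_bc = 2295, noise_sd = 0
  )
  fit <- fit_production(
    syn$profile, bench_params,
    max_zones = 4, top_bc = 2295, bottom_flux = 0
  )
  expect_equal(fit$k, 2)
  expect_lt(max(abs(fit$zones$rate / truth_rates - 1)), 1e-6)
  expect_lt(
    abs(sediment_water_flux(fit) / syn$truth$flux_top - 1), 1e-6
  )
})

test_that("a linear profile is pure diffusion: one zone, no production", {
  phi <- bench_params$porosity
  d <- bench_params$d_mol
  slope <- 12 # umol L-1 cm-1
  depths <- seq(1, 20, by = 1)
  profile <- tibble::tibble(
    depth_cm = depths, conc_umol_l = 2295 + slope * depths
  )
  flux_in <- phi * d * slope * 10 # upward supply from below, umol m-2 hr-1
  fit <- fit_production(
    profile, bench_params,
    max_zones = 3, top_bc = 2295, bottom_flux = flux_in
  )
  expect_equal(fit$k, 1)
  expect_lt(abs(fit$zones$rate), 1e-9)
  expect_equal(sediment_water_flux(fit), flux_in, tolerance = 1e-9)
})

test_that("a consumption-over-production profile fits with the right sign pattern", {
  syn <- synth_porewater(
    depths = seq(1.25, 30, by = 1.25), boundaries = c(0, 15, 30),
    rates = c(-0.004, 0.006), params = bench_params,
    top_bc = 2295, noise_sd = 0
  )
  fit <- fit_production(
    syn$profile, bench_params,
    max_zones = 2, top_bc = 2295, bottom_flux = 0
  )
  expect_lt(fit$zones$rate[1], 0)
  expect_gt(fit$zones$rate[2], 0)
})

test_that("the top flux equals production integral plus bottom input", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      k <- sample(1:3, 1)
      depth <- sample(c(20, 24, 30), 1)
      rates <- stats::runif(k, -0.01, 0.01)
      bottom <- stats::runif(1, -1, 1)
      bounds <- seq(0, depth, length.out = k + 1)
      sol <- forward_solve(
        bench_params, bounds, rates,
        top_bc = 2295, bottom_flux = bottom
      )
      syn_fit <- fit_production(
        tibble::tibble(depth_cm = sol$depth, conc_umol_l = pmax(sol$conc, 0)),
        bench_params,
        max_zones = k, top_bc = 2295, bottom_flux = bottom
      )
      phi <- bench_params$porosity
      integral <- sum(0.5 * phi * syn_fit$grid$rate) * 10
      expect_lt(abs(syn_fit$flux_top - (integral + bottom)), 1e-9)
    }
  })
})

test_that("fitted fluxes are stable under grid refinement", {
  syn <- synth_porewater(
    depths = seq(1.25, 30, by = 1.25), boundaries = c(0, 15, 30),
    rates = c(-0.004, 0.006), params = bench_params,
    top_bc = 2295, noise_sd = 0.3, seed = 11
  )
  coarse <- fit_production(
    syn$profile, bench_params,
    max_zones = 2, top_bc = 2295, bottom_flux = 0, h = 0.5
  )
  fine <- fit_production(
    syn$profile, bench_params,
    max_zones = 2, top_bc = 2295, bottom_flux = 0, h = 0.25
  )
  expect_lt(abs(fine$flux_top / coarse$flux_top - 1), 0.005)
})

test_that("zone selection resists overfitting pure noise", {
  ks <- vapply(1:200, function(s) {
    syn <- synth_porewater(
      depths = seq(1.25, 30, by = 1.25), boundaries = c(0, 30),
      rates = 0, params = bench_params, top_bc = 2295,
      noise_sd = 5, seed = 1000 + s
    )
    fit_production(
      syn$profile, bench_params,
      max_zones = 3, top_bc = 2295, bottom_flux = 0
    )$k
  }, numeric(1))
  expect_gte(mean(ks == 1), 0.95)
})

test_that("sulfide-like profiles yield upward fluxes below the consumption zone", {
  # strong sulfate-reduction source at depth, consumption near the interface
  syn <- synth_porewater(
    depths = seq(1.25, 30, by = 1.25), boundaries = c(0, 15, 30),
    rates = c(-0.002, 0.01), params = bench_params,
    top_bc = 0, delta_source = NULL, noise_sd = 0
  )
  fit <- fit_production(
    syn$profile, bench_params,
    max_zones = 2, top_bc = 0, bottom_flux = 0
  )
  # upward flux across the top of the production zone
  phi <- bench_params$porosity
  flux_at_15 <- sum(0.5 * phi * fit$grid$rate[fit$grid$depth > 15]) * 10
  expect_gt(flux_at_15, 0)
})

test_that("tidiers expose the zone table and fit summary", {
  syn <- synth_porewater(
    depths = seq(1.25, 30, by = 1.25), boundaries = c(0, 15, 30),
    rates = c(-0.004, 0.006), params = bench_params,
    top_bc = 2295, noise_sd = 0
  )
  fit <- fit_production(
    syn$profile, bench_params,
    max_zones = 2, top_bc = 2295, bottom_flux = 0
  )
  td <- tidy(fit)
  expect_identical(names(td), c("zone", "top", "bottom", "rate"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$flux_top, sediment_water_flux(fit))
})
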
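site <- water_state(2596, 2295, 38, 26)
site_comp <- sediment_composition()

test_that("sediment accumulation converts to molar burial by either convention", {
  # pure carbonate: 1042 g m-2 yr-1 is 10.4 mol CaCO3 m-2 yr-1
  pure_ic <- sediment_composition(f_ic = 100, f_oc = 0, f_crs = 0, f_fe = 0)
  r <- burial_rates(1042, pure_ic)
  expect_equal(
    r$rate_mol_m2_yr[r$process == "caco3_burial"], 10.4,
    tolerance = 0.005
  )

  r0 <- burial_rates(0, site_comp)
  expect_true(all(r0$rate_mol_m2_yr == 0))

  molar <- burial_rates(100, site_comp)
  mass <- burial_rates(
    100, sediment_composition(interpretation = "mass")
  )
  get <- function(tb, p) tb$rate_mol_m2_yr[tb$process == p]
  expect_equal(get(molar, "caco3_burial"), get(mass, "caco3_burial"))
  expect_equal(
    get(mass, "oc_burial") / get(molar, "oc_burial"),
    100.09 / 12.011
  )
})

test_that("composition validation enforces the measured-sediment simplex", {
  expect_error(sediment_composition(f_oc = -1), ">= 0")
  expect_error(sediment_composition(f_ic = 50), "outside")
})

test_that("excess CO2 is zero without burial and grows linearly with accumulation", {
  curve <- excess_co2_curve(
    budget_config(sar = c(0, 10, 100, 200, 460, 1000)), site_comp, site
  )
  expect_equal(curve$excess_co2[curve$sar == 0], 0)
  expect_true(all(diff(curve$excess_co2[order(curve$sar)]) > 0))
  # exact linearity of the linearized mode
  expect_equal(
    curve$excess_co2[curve$sar == 200],
    2 * curve$excess_co2[curve$sar == 100]
  )
})

test_that("per-process excess terms sum to the total", {
  curve <- excess_co2_curve(budget_config(sar = c(10, 460)), site_comp, site)
  expect_lt(
    max(abs(
      curve$excess_ic + curve$excess_oc + curve$excess_crs + curve$excess_fe -
        curve$excess_co2
    )),
    1e-9
  )
})

test_that("attribution shares are invariant to water mass and accumulation rate", {
  shares <- purrr::map_dfr(c(1e2, 1e3, 1e4), function(w) {
    curve <- excess_co2_curve(
      budget_config(sar = c(10, 460, 1000), water_mass = w), site_comp, site
    )
    attribute_contributions(curve)
  })
  expect_lt(max(shares$share_oc) - min(shares$share_oc), 1e-9)
  expect_lt(max(shares$share_redox) - min(shares$share_redox), 1e-9)
  expect_lt(max(shares$share_ic) - min(shares$share_ic), 1e-9)
  expect_equal(
    shares$share_ic + shares$share_oc + shares$share_redox,
    rep(100, nrow(shares))
  )
})

test_that("a carbonate-only sediment attributes everything to calcification", {
  pure_ic <- sediment_composition(f_ic = 100, f_oc = 0, f_crs = 0, f_fe = 0)
  curve <- excess_co2_curve(budget_config(sar = 100), pure_ic, site)
  shares <- attribute_contributions(curve)
  expect_equal(shares$share_ic, 100)
  expect_equal(shares$share_oc, 0)
})

test_that("calcification excess exceeds the organic-carbon sink at least fourfold", {
  curve <- excess_co2_curve(budget_config(sar = 100), site_comp, site)
  expect_gt(curve$excess_ic / abs(curve$excess_oc), 4)
})

test_that("linearized and re-solved budgets agree for small effective perturbations", {
  # large water mass keeps the TA/DIC anomalies within the linear regime
  cfg_lin <- budget_config(sar = c(10, 100), water_mass = 1e5)
  cfg_full <- budget_config(
    sar = c(10, 100), water_mass = 1e5, mode = "full_resolve"
  )
  lin <- excess_co2_curve(cfg_lin, site_comp, site)
  full <- excess_co2_curve(cfg_full, site_comp, site)
  expect_lt(max(abs(lin$excess_co2 / full$excess_co2 - 1)), 0.05)
})

test_that("the balancing organic-carbon fraction zeroes the excess", {
  bal <- solve_balancing_oc(site_comp, site)
  expect_lt(abs(bal$excess_co2), 1e-9)
  expect_true(bal$feasible)
  expect_equal(bal$f_oc + bal$f_ic, 97.5 + 2.1)

  # direct evaluation at the returned composition confirms the root
  comp_root <- tibble::tibble(
    f_ic = bal$f_ic, f_oc = bal$f_oc, f_crs = 0.3, f_fe = 0.5,
    interpretation = "molar"
  )
  curve <- excess_co2_curve(budget_config(sar = 100), comp_root, site)
  expect_lt(abs(curve$excess_co2), 1e-6)
})

test_that("a sediment without carbonate needs no balancing organic carbon", {
  no_ic <- sediment_composition(f_ic = 0, f_oc = 99.2, f_crs = 0.3, f_fe = 0.5)
  bal <- solve_balancing_oc(no_ic, site)
  expect_equal(bal$f_oc, 0)
  expect_true(bal$feasible) # redox-only burial consumes CO2
})

test_that("a capped infeasible scenario reports the residual of the capped composition", {
  # redox amendment with the OC cap below the root: no balance attainable
  capped <- solve_balancing_oc(
    site_comp, site,
    redox_scale = 45, f_oc_max = 5 * 2.1
  )
  expect_false(capped$feasible)
  expect_equal(capped$f_oc, 10.5)
  # independent single evaluation of the budget at the capped composition
  comp_cap <- tibble::tibble(
    f_ic = 97.5 + 2.1 - 10.5, f_oc = 10.5,
    f_crs = 0.3 * 45, f_fe = 0.5 * 45, interpretation = "molar"
  )
  direct <- excess_co2_curve(budget_config(sar = 100), comp_cap, site)
  expect_equal(capped$excess_co2, direct$excess_co2, tolerance = 1e-9)
  expect_gt(capped$excess_co2, 0)
})

test_that("scaling the redox fractions moves the balance point down", {
  base <- solve_balancing_oc(site_comp, site, redox_scale = 1)
  amended <- solve_balancing_oc(site_comp, site, redox_scale = 45)
  expect_lt(amended$f_oc, base$f_oc)
  expect_true(amended$feasible)
})
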
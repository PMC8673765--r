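Package: carbbudget
Title: Carbon-Alkalinity Budgeting for Carbonate Sediment Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Budgets the air-water CO2 implications of sediment burial in
    shallow carbonate systems such as seagrass meadows. Solves the seawater
    CO2 system from total alkalinity and dissolved inorganic carbon,
    evaluates alkalinity and DIC buffer factors, converts sediment
    accumulation and composition into per-process TA/DIC anomalies and
    water-column excess CO2 with scenario solvers, translates between
    air-water CO2 fluxes and steady-state excess concentrations, inverts
    pore-water concentration profiles for zone-wise net production with a
    steady-state diffusion-reaction model, and provides continuous-flow
    incubation flux arithmetic, Keeling-plot endmember regression, and
    synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
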
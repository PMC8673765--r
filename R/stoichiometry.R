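# Per-process TA/DIC stoichiometry of the sediment burial budget.
# Coefficients are the effect on water-column TA and DIC, in moles per mole
# of process currency (mol CaCO3, mol OC-C, mol CRS-S, mol Fe), with reaction
# rows normalized per mole of the buried/transformed species.

#' Composite stoichiometry for chromium-reducible sulfur burial
#'
#' Net sulfate reduction followed by permanent burial of the reduced sulfur
#' generates alkalinity, but how much depends on the buried phase. Per mole
#' of buried S, the component half-reactions contribute, on the water column:
#' sulfate reduction (dTA +1, dDIC +1, the 1:1 ratio of sulfide production),
#' pyritization to FeS2 (dTA 0), and partial reoxidation/burial as elemental
#' S0 (dTA +2). The composite coefficient is the fraction-weighted sum; the
#' conventional equal split between FeS2 and S0 yields dTA:dDIC = 2:1.
#'
#' @param frac_fes2 Fraction of CRS buried as pyrite (FeS2).
#' @param frac_s0 Fraction buried as elemental sulfur (S0). Must satisfy
#'   `frac_fes2 + frac_s0 = 1`.
#'
#' @return A one-row tibble with columns `process`, `currency`,
#'   `dta_per_mol`, `ddic_per_mol`.
#' @export
#' @examples
#' crs_composite(0.5, 0.5) # dTA:dDIC = 2:1
crs_composite <- function(frac_fes2 = 0.5, frac_s0 = 0.5) {
  stopifnot(length(frac_fes2) == 1, length(frac_s0) == 1)
  if (frac_fes2 < 0 || frac_fes2 > 1 || frac_s0 < 0 || frac_s0 > 1 ||
    abs(frac_fes2 + frac_s0 - 1) > 1e-12) {
    stop("CRS burial fractions must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  # per mol S: sulfate reduction (+1, +1); FeS2 burial (0, 0); S0 burial (+2, 0)
  tibble::tibble(
    process = "crs_burial",
    currency = "mol S",
    dta_per_mol = 1 + 0 * frac_fes2 + 2 * frac_s0,
    ddic_per_mol = 1
  )
}

#' Registry of burial-budget process stoichiometries
#'
#' Returns the per-process molar TA/DIC coefficients used by the budget:
#' CaCO3 burial (-2, -1 per mol CaCO3: precipitation consumes two
#' equivalents of alkalinity and one carbon), organic-carbon burial
#' (0, -1 per mol C: net primary production fixes one DIC with negligible
#' net TA effect), composite CRS burial (see [crs_composite()]), iron
#' reduction (+2, +0.5 per mol Fe, i.e. TA:DIC of 8:2 per 4 Fe reduced),
#' and canonical denitrification (+0.8, +1 per mol OC-C). Denitrification
#' carries a default weight of 0: the measured net N2 flux was
#' indistinguishable from zero, so it contributes no term to the default
#' budget while remaining available for scenario work.
#'
#' @param crs_split Length-2 numeric, `c(frac_fes2, frac_s0)`, passed to
#'   [crs_composite()].
#'
#' @return A tibble with columns `process`, `currency`, `dta_per_mol`,
#'   `ddic_per_mol`, `default_weight`.
#' @export
#' @examples
#' stoich_ledger()
stoich_ledger <- function(crs_split = c(0.5, 0.5)) {
  crs <- crs_composite(crs_split[1], crs_split[2])
  tibble::tibble(
    process = c(
      "caco3_burial", "oc_burial", "crs_burial", "fe_reduction",
      "denitrification"
    ),
    currency = c("mol CaCO3", "mol C", "mol S", "mol Fe", "mol C"),
    dta_per_mol = c(-2, 0, crs$dta_per_mol, 2, 0.8),
    ddic_per_mol = c(-1, -1, crs$ddic_per_mol, 0.5, 1),
    default_weight = c(1, 1, 1, 1, 0)
  )
}

#' Look up one process in the stoichiometry ledger
#'
#' @param process Process identifier, one of the `process` values of
#'   [stoich_ledger()].
#' @inheritParams stoich_ledger
#' @return A one-row tibble (subset of the ledger).
#' @export
#' @examples
#' stoich_lookup("caco3_burial")
stoich_lookup <- function(process, crs_split = c(0.5, 0.5)) {
  ledger <- stoich_ledger(crs_split)
  out <- ledger[ledger$process == process, ]
  if (nrow(out) == 0) {
    stop(
      sprintf(
        "unknown process '%s'; registered: %s",
        process, paste(ledger$process, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  out
}
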
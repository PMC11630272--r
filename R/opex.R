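# Annual operating-cost components.

#' Annual raw-material cost
#'
#' Feedstock demand times the region's collection/purchase price. Glucose
#' runs at $500/MT (USA, EU) and $400/MT (SEA); glycerin at $600/$500;
#' waste-stream prices are collection costs (e.g. corn stover $42.50/MT,
#' palm EFB $48.82/MT).
#'
#' @param demand_mt Raw feedstock demand, MT/yr.
#' @param a An `assumption_set` (for the regional price table).
#' @param feedstock,region Labels resolving against the set. An unavailable
#'   feedstock-region pair is an error.
#' @return USD/yr.
#' @export
raw_material_cost <- function(demand_mt, a, feedstock, region) {
  stopifnot(demand_mt >= 0)
  demand_mt * feedstock_price(a, feedstock, region)
}

#' Annual preprocessing cost
#'
#' Cost of converting raw feedstock to fermentable glucose (pretreatment and
#' enzymatic hydrolysis), charged per tonne of raw feedstock; zero for
#' direct sugars. The published range runs from $38.10/MT (bread waste) to
#' $80.34/MT (corn stover).
#'
#' @param raw_mt Raw feedstock processed, MT/yr.
#' @param feedstock One-row feedstock tibble.
#' @return USD/yr.
#' @export
preprocessing_cost <- function(raw_mt, feedstock) {
  stopifnot(raw_mt >= 0)
  if (feedstock$category == "direct_sugar") return(0)
  raw_mt * feedstock$preprocessing_cost_usd_per_mt
}

#' Annual facilities cost
#'
#' Energy, waste treatment, and maintenance, modeled as a fixed fraction of
#' capital expense — 5.0% by default (close to the 5.45% used in NREL's
#' bioethanol model).
#'
#' @param capex_usd Capital expense, USD (> 0).
#' @param rate Fraction of CapEx per year, default 0.050.
#' @return USD/yr.
#' @export
facilities_cost <- function(capex_usd, rate = 0.050) {
  if (capex_usd <= 0) {
    abort("capex_usd must be > 0", class = "oleotea_validation_error")
  }
  rate * capex_usd
}

#' Other annual cost
#'
#' Insurance, compliance, and legal, modeled as a fraction of the annual
#' facilities cost (16.9% by default).
#'
#' @param facilities_usd Annual facilities cost, USD/yr (>= 0).
#' @param rate Fraction of facilities cost, default 0.169.
#' @return USD/yr.
#' @export
other_annual_cost <- function(facilities_usd, rate = 0.169) {
  stopifnot(facilities_usd >= 0)
  rate * facilities_usd
}

#' Miscellaneous operating costs
#'
#' Media is charged per liter of media turned over (batch: capacity x
#' batches; continuous: capacity x D x operating days — the media-turnover
#' normalization that makes the two modes comparable). Recovery is charged
#' per kg of recovered lipid, waste handling per tonne of raw feedstock;
#' consumables and disposables are annual lump sums passed through.
#'
#' @param mb A `mass_balance`.
#' @param plant A [plant_spec()].
#' @param rates Misc-OpEx rate list (an assumption set's `misc_opex`).
#' @return Named list of components (USD/yr): `media`, `recovery`, `waste`,
#'   `consumables`, `disposables`.
#' @export
misc_costs <- function(mb, plant, rates) {
  stopifnot(all(unlist(rates[MISC_OPEX_KEYS]) >= 0))
  list(
    media = rates$media_usd_per_batch_l * plant$fermentation_capacity_l *
      media_turnovers_per_year(plant),
    recovery = rates$recovery_usd_per_kg_lipid *
      mb$lipid_out_mt_per_year * 1000,
    waste = rates$waste_usd_per_mt_feedstock *
      mb$raw_feedstock_demand_mt_per_year,
    consumables = rates$consumables_usd_per_year,
    disposables = rates$disposables_usd_per_year
  )
}
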
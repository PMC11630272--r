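# Fermentation mass balance: plant spec + productivity scenario to annual
# lipid output and upstream feedstock demand, for batch and continuous modes.

#' Specify a production plant
#'
#' @param fermentation_capacity_l Total working volume, L. The modeled range
#'   is 50k-15M L (ten 1.5M-L reactors at the top end); outside it
#'   predictions are flagged as extrapolations.
#' @param region Region label (`"USA"`, `"EU"`, `"SEA"`).
#' @param feedstock Feedstock label resolving against the assumption set.
#' @param mode `"batch"` or `"continuous"`.
#' @param n_reactors Positive reactor count; defaults to 1.5M-L units.
#' @param fermentation_days Duration of one batch (default 5, the typical
#'   bench-scale batch length).
#' @param turnaround_days Clean/sterilize/refill time per batch (default 1).
#' @param utilization_days_per_year Operating days per year (default 330,
#'   <= 365).
#' @param dilution_rate_per_day Continuous-mode media turnover rate
#'   (default 0.14/d, about one full media exchange per week).
#' @param recovery_yield_fraction Fraction of intracellular lipid recovered
#'   downstream (hexane extraction), in (0, 1]; default 0.95.
#' @return A `plant_spec` (named list).
#' @examples
#' plant_spec(15e6, "SEA", "palm_efb")
#' @export
plant_spec <- function(fermentation_capacity_l,
                       region,
                       feedstock,
                       mode = c("batch", "continuous"),
                       n_reactors = NULL,
                       fermentation_days = 5,
                       turnaround_days = 1,
                       utilization_days_per_year = 330,
                       dilution_rate_per_day = 0.14,
                       recovery_yield_fraction = 0.95) {
  mode <- match.arg(mode)
  stopifnot(fermentation_capacity_l > 0,
            fermentation_days + turnaround_days > 0,
            utilization_days_per_year > 0,
            utilization_days_per_year <= 365,
            dilution_rate_per_day > 0,
            recovery_yield_fraction > 0, recovery_yield_fraction <= 1)
  if (is.null(n_reactors)) {
    n_reactors <- max(1L, ceiling(fermentation_capacity_l / 1.5e6))
  }
  stopifnot(n_reactors >= 1)
  structure(
    list(fermentation_capacity_l = fermentation_capacity_l,
         region = region,
         feedstock = feedstock,
         mode = mode,
         n_reactors = as.integer(n_reactors),
         fermentation_days = fermentation_days,
         turnaround_days = turnaround_days,
         utilization_days_per_year = utilization_days_per_year,
         dilution_rate_per_day = dilution_rate_per_day,
         recovery_yield_fraction = recovery_yield_fraction),
    class = "plant_spec"
  )
}

#' Batches per reactor-year
#'
#' Utilization days divided by the batch cycle (fermentation + turnaround).
#' Not rounded: a fractional trailing batch contributes pro rata.
#'
#' @param plant A batch-mode [plant_spec()].
#' @return Batches per year.
#' @examples
#' batches_per_year(plant_spec(1e6, "USA", "glucose")) # 330 / (5 + 1) = 55
#' @export
batches_per_year <- function(plant) {
  if (plant$mode != "batch") {
    abort("batches_per_year is defined for batch-mode plants only",
          class = "oleotea_mode_error")
  }
  plant$utilization_days_per_year /
    (plant$fermentation_days + plant$turnaround_days)
}

# Media volumes turned over per year, the quantity media cost is charged on.
# Batch: one working volume per batch. Continuous: D volumes per operating
# day, which normalizes batch and continuous processes onto the same
# media-usage scale.
media_turnovers_per_year <- function(plant) {
  switch(plant$mode,
         batch = batches_per_year(plant),
         continuous = plant$dilution_rate_per_day *
           plant$utilization_days_per_year)
}

#' Annual recovered lipid output
#'
#' Batch: `capacity x titer x batches_per_year x recovery / 1e6` (g to MT).
#' Continuous: the broth leaving the reactor at dilution rate `D` carries the
#' scenario titer, so output is
#' `capacity x titer x D x utilization_days x recovery / 1e6`. The two modes
#' coincide exactly when `D x utilization_days` equals the number of batches.
#'
#' @param plant A [plant_spec()].
#' @param scen One-row scenario tibble (columns `titer_g_per_l`,
#'   `actual_yield_fraction`, `theoretical_yield_g_per_g`) for the plant's
#'   carbon source.
#' @return Recovered lipid, MT/yr.
#' @export
annual_lipid_output <- function(plant, scen) {
  titer <- scen$titer_g_per_l
  if (is.null(titer) || length(titer) == 0 || is.na(titer)) {
    abort("scenario has no titer for the plant's carbon source",
          class = "oleotea_missing_feed_error")
  }
  turnovers <- media_turnovers_per_year(plant)
  plant$fermentation_capacity_l * titer * turnovers *
    plant$recovery_yield_fraction / 1e6
}

#' Fermentable-glucose demand for a lipid output
#'
#' Inverts the yield chain: glucose (or glycerol) equivalents =
#' `lipid / (theoretical_yield x actual_yield_fraction x (1 - drag))`.
#' The yield drag models inhibitory metabolites left by hydrolysis of waste
#' feedstocks (capped at 3%). Downstream recovery losses are accounted for
#' in [annual_lipid_output()], not here: demand is driven by lipid made in
#' the broth, so callers pass the pre-recovery (in-broth) lipid mass.
#'
#' @param lipid_mt Lipid produced in the broth, MT.
#' @param scen One-row scenario tibble for the plant's carbon source.
#' @param drag Yield-drag fraction in `[0, 0.03]`.
#' @return Glucose-equivalent demand, MT.
#' @export
glucose_demand <- function(lipid_mt, scen, drag = 0) {
  stopifnot(drag >= 0, drag <= 0.03)
  eff_yield <- scen$theoretical_yield_g_per_g * scen$actual_yield_fraction *
    (1 - drag)
  if (eff_yield <= 0) {
    abort("effective yield is zero; check theoretical yield and actual-yield fraction",
          class = "oleotea_validation_error")
  }
  lipid_mt / eff_yield
}

#' Raw feedstock demand for a glucose demand
#'
#' Divides by the preprocessing efficiency (grams of fermentable glucose per
#' gram of raw feedstock). Identity for direct sugars.
#'
#' @param glucose_mt Glucose-equivalent demand, MT.
#' @param feedstock One-row feedstock tibble.
#' @return Raw feedstock demand, MT.
#' @export
raw_feedstock_demand <- function(glucose_mt, feedstock) {
  eff <- feedstock$preprocessing_efficiency_g_per_g
  stopifnot(eff > 0, eff <= 1)
  glucose_mt / eff
}

#' Farmland footprint of a feedstock demand
#'
#' @param feedstock_mt Annual feedstock demand, tons/yr.
#' @param yield_tons_per_acre Dry-ton yield per acre (3.75 for corn stover).
#' @return Acres of farmland.
#' @examples
#' farmland_acres(562500, 3.75) # 150,000 acres
#' @export
farmland_acres <- function(feedstock_mt, yield_tons_per_acre) {
  stopifnot(yield_tons_per_acre > 0)
  feedstock_mt / yield_tons_per_acre
}

#' Full plant mass balance
#'
#' Chains output, glucose demand, and raw feedstock demand for one plant,
#' scenario, and feedstock. Feedstock demand is driven by the lipid made in
#' the broth (before recovery losses), while the saleable output is the
#' recovered fraction.
#'
#' @inheritParams annual_lipid_output
#' @param feedstock One-row feedstock tibble.
#' @return A `mass_balance` list: `batches_per_year` (media turnovers for
#'   continuous plants), `lipid_out_mt_per_year`, `glucose_demand_mt_per_year`,
#'   `raw_feedstock_demand_mt_per_year`.
#' @export
mass_balance <- function(plant, scen, feedstock) {
  lipid_out <- annual_lipid_output(plant, scen)
  lipid_in_broth <- lipid_out / plant$recovery_yield_fraction
  glucose <- glucose_demand(lipid_in_broth, scen,
                            drag = feedstock$yield_drag_fraction)
  raw <- raw_feedstock_demand(glucose, feedstock)
  structure(
    list(batches_per_year = media_turnovers_per_year(plant),
         lipid_out_mt_per_year = lipid_out,
         glucose_demand_mt_per_year = glucose,
         raw_feedstock_demand_mt_per_year = raw),
    class = "mass_balance"
  )
}
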
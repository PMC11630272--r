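# Orchestration: single scenario runs, full grid sweeps, and reports.
# The engine is fully deterministic: identical inputs give identical results.

#' Run one techno-economic scenario
#'
#' Deterministic composition of the whole model: CapEx prediction (with the
#' feedstock multiplier) feeds depreciation and facilities costs; the labor
#' scaling model gives FTEs and labor cost; the fermentation mass balance
#' gives annual output and feedstock demand; operating costs are assembled
#' into the closed component set; and the product's regional commodity price
#' turns COGS into a gross margin. Product-specific strain and recovery
#' differences are applied as a uniform multiplier on the baseline cost
#' components (`cost_adjustment_factor`).
#'
#' A plant whose capacity exceeds the feedstock's availability cap (e.g.
#' bread waste above 4.5M L) returns a flagged result, not an error.
#'
#' @param a An `assumption_set`.
#' @param plant A [plant_spec()].
#' @param scenario Productivity-scenario label (e.g. `"Current Tech Base
#'   Case"`).
#' @param product End-market label (e.g. `"crude_palm_oil"`).
#' @return A `scenario_result`: echoed descriptors plus `annual_output_mt`,
#'   `cogs_usd_per_kg`, `price_usd_per_mt`, `gross_margin_pct`, the
#'   `cost_breakdown`, the mass balance, FTEs, CapEx, and `flags`.
#' @examples
#' a <- default_assumption_set()
#' r <- run_scenario(a, plant_spec(15e6, "SEA", "palm_efb"),
#'                   "Current Tech Base Case", "crude_palm_oil")
#' r$cogs_usd_per_kg
#' @export
run_scenario <- function(a, plant, scenario, product) {
  region <- lookup_region(a, plant$region)
  feedstock <- lookup_feedstock(a, plant$feedstock)
  scen <- lookup_scenario(a, scenario, feedstock$carbon_source)
  prod <- lookup_product(a, product, plant$region)

  flags <- character()
  cap <- feedstock$availability_cap_l
  if (!is.na(cap) && plant$fermentation_capacity_l > cap) {
    flags <- c(flags, sprintf(
      "availability_cap_exceeded: %s supports at most %.3g L of capacity",
      feedstock$name, cap))
  }

  capex <- withCallingHandlers(
    predict_capex(a$capex_model, plant, feedstock),
    oleotea_extrapolation_warning = function(w) {
      flags <<- c(flags, paste0("capex_extrapolation: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  depreciation <- annual_depreciation(capex, a$depreciation_years)
  facilities <- facilities_cost(capex, a$facilities_rate)
  other <- other_annual_cost(facilities, a$other_rate)
  ftes <- predict_ftes(a$labor_model, plant$fermentation_capacity_l)
  labor <- annual_labor_cost(ftes, region)

  mb <- mass_balance(plant, scen, feedstock)
  raw <- raw_material_cost(mb$raw_feedstock_demand_mt_per_year, a,
                           feedstock$name, plant$region)
  preproc <- preprocessing_cost(mb$raw_feedstock_demand_mt_per_year, feedstock)
  misc <- misc_costs(mb, plant, a$misc_opex)

  components <- c(
    raw_material = raw, preprocessing = preproc, media = misc$media,
    labor = labor, depreciation = depreciation, facilities = facilities,
    recovery = misc$recovery, consumables = misc$consumables,
    disposables = misc$disposables, waste = misc$waste, other = other
  ) * prod$cost_adjustment_factor

  breakdown <- cost_breakdown(components, mb$lipid_out_mt_per_year)
  cogs_kg <- cogs_per_kg(breakdown)
  margin <- gross_margin_pct(prod$price_usd_per_mt, cogs_kg * 1000)

  structure(
    list(region = plant$region,
         feedstock = plant$feedstock,
         capacity_l = plant$fermentation_capacity_l,
         mode = plant$mode,
         scenario = scenario,
         product = product,
         annual_output_mt = mb$lipid_out_mt_per_year,
         cogs_usd_per_kg = cogs_kg,
         price_usd_per_mt = prod$price_usd_per_mt,
         gross_margin_pct = margin,
         capex_usd = capex,
         ftes = ftes,
         mass_balance = mb,
         breakdown = breakdown,
         flags = flags),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s | %s | %.3g L | %s | %s | %s\n",
              x$region, x$feedstock, x$capacity_l, x$mode, x$scenario,
              x$product))
  cat(sprintf("  output %.0f MT/yr | COGS $%.2f/kg | price $%.0f/MT | gross margin %.1f%%\n",
              x$annual_output_mt, x$cogs_usd_per_kg, x$price_usd_per_mt,
              x$gross_margin_pct))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Default scenario grid
#'
#' The documented reconstruction of the full sweep: a seven-point capacity
#' ladder (50k, 150k, 500k, 1.5M, 4.5M, 10M, 15M L) crossed with all
#' regions, feedstocks, productivity scenarios, products, and both
#' fermentation modes. Availability constraints (feedstock-by-region and the
#' bread-waste capacity cap) are applied by [sweep_scenarios()], not here.
#'
#' @param a An `assumption_set`.
#' @return A `scenario_grid`: named list of axis vectors.
#' @export
default_grid <- function(a) {
  structure(
    list(capacities_l = c(5e4, 1.5e5, 5e5, 1.5e6, 4.5e6, 1e7, 1.5e7),
         regions = a$regions$name,
         feedstocks = a$feedstocks$name,
         scenarios = unique(a$scenarios$scenario),
         products = a$products$name,
         modes = c("batch", "continuous")),
    class = "scenario_grid"
  )
}

#' Sweep a scenario grid
#'
#' Runs [run_scenario()] over every feasible cell of the grid. Cells whose
#' feedstock is not available in the region, or whose capacity exceeds the
#' feedstock's availability cap, are excluded (listed in the `infeasible`
#' attribute), not errored. Results come back in a stable lexicographic
#' ordering over (region, feedstock, capacity, scenario, product, mode)
#' regardless of the input order of the axes.
#'
#' @param a An `assumption_set`.
#' @param grid A [default_grid()]-style list of axes.
#' @param ... Passed to [plant_spec()] (e.g. non-default utilization).
#' @return Tibble with one row per feasible scenario (breakdowns in a
#'   `breakdown` list-column; flags collapsed to a string) and the excluded
#'   cells in `attr(, "infeasible")`.
#' @export
sweep_scenarios <- function(a, grid = default_grid(a), ...) {
  cells <- tidyr::expand_grid(
    region = sort(grid$regions),
    feedstock = sort(grid$feedstocks),
    capacity_l = sort(grid$capacities_l),
    scenario = sort(grid$scenarios),
    product = sort(grid$products),
    mode = sort(grid$modes)
  )
  fp_key <- paste(a$feedstock_prices$feedstock, a$feedstock_prices$region)
  available <- paste(cells$feedstock, cells$region) %in% fp_key
  caps <- a$feedstocks$availability_cap_l[match(cells$feedstock,
                                                a$feedstocks$name)]
  within_cap <- is.na(caps) | cells$capacity_l <= caps
  feasible <- available & within_cap

  infeasible <- cells[!feasible, ]
  infeasible$reason <- ifelse(!available[!feasible],
                              "feedstock_not_available_in_region",
                              "capacity_exceeds_availability_cap")
  cells <- cells[feasible, ]
  if (nrow(cells) == 0) {
    warn("no feasible cells in grid", class = "oleotea_empty_result_warning")
  }

  results <- purrr::pmap(cells, function(region, feedstock, capacity_l,
                                         scenario, product, mode) {
    run_scenario(a, plant_spec(capacity_l, region, feedstock, mode = mode, ...),
                 scenario, product)
  })
  out <- cells
  out$annual_output_mt <- vapply(results, `[[`, numeric(1), "annual_output_mt")
  out$cogs_usd_per_kg <- vapply(results, `[[`, numeric(1), "cogs_usd_per_kg")
  out$price_usd_per_mt <- vapply(results, `[[`, numeric(1), "price_usd_per_mt")
  out$gross_margin_pct <- vapply(results, `[[`, numeric(1), "gross_margin_pct")
  out$capex_usd <- vapply(results, `[[`, numeric(1), "capex_usd")
  out$ftes <- vapply(results, `[[`, numeric(1), "ftes")
  out$flags <- vapply(results, function(r) paste(r$flags, collapse = "; "),
                      character(1))
  out$breakdown <- lapply(results, `[[`, "breakdown")
  attr(out, "infeasible") <- infeasible
  out
}

#' Cost-breakdown report for one scenario
#'
#' @param r A `scenario_result` from [run_scenario()].
#' @param digits Rounding for the displayed share percentages (default 2).
#' @return Tibble with `component`, `usd_per_year`, `usd_per_kg`, and
#'   `share_pct` (percentages summing to 100 at display precision).
#' @export
breakdown_report <- function(r, digits = 2) {
  b <- r$breakdown
  shares <- cost_shares(b)
  tibble::tibble(
    component = names(b$components),
    usd_per_year = unname(b$components),
    usd_per_kg = unname(b$components) / (b$annual_output_mt * 1000),
    share_pct = round(unname(shares) * 100, digits)
  )
}

#' Write sweep results to a delimited file
#'
#' Drops the breakdown list-column; columns and their order are stable and
#' machine-readable.
#'
#' @param results Tibble from [sweep_scenarios()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  flat <- results[setdiff(names(results), "breakdown")]
  readr::write_csv(flat, path)
  invisible(path)
}

#' Read the packaged commodity price and scale-production-cost table
#'
#' Commodity sales prices (USD/MT) for the four end markets alongside
#' production costs at scale in SEA (10 x 1.5M L, palm-biomass feedstock)
#' under each productivity scenario — the inputs of the gross-margin
#' analysis.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Tibble with `product`, `commodity_price_usd_per_mt`, and one
#'   production-cost column per productivity scenario.
#' @export
read_commodity_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "commodity_prices_costs.csv",
                        package = "oleotea", mustWork = TRUE)
  }
  readr::read_csv(path, show_col_types = FALSE)
}
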
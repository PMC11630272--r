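# Assumption sets: the complete, validated bundle of regional, feedstock,
# product, scenario, and plant-cost parameters that drives one model run.

ASSUMPTION_KEYS <- c(
  "schema_version", "regions", "feedstocks", "feedstock_prices", "products",
  "product_prices", "scenarios", "capex_model", "labor_model", "misc_opex",
  "facilities_rate", "other_rate", "depreciation_years", "calibration_needed"
)

MISC_OPEX_KEYS <- c(
  "media_usd_per_batch_l", "recovery_usd_per_kg_lipid",
  "consumables_usd_per_year", "disposables_usd_per_year",
  "waste_usd_per_mt_feedstock"
)

new_assumption_set <- function(x) {
  x <- x[ASSUMPTION_KEYS]
  structure(x, class = "assumption_set")
}

#' Default assumption set
#'
#' Builds the packaged assumption set: three production regions (USA, EU,
#' SEA), seven feedstocks (glucose, glycerin, corn stover, sugar beet,
#' cassava, bread waste, palm empty fruit bunches), four end markets, and the
#' four named productivity scenarios. Feedstock and product prices, the
#' preprocessing cost range, the facilities rate (5.0% of CapEx), the "other
#' annual cost" rate (16.9% of facilities), and 20-year straight-line
#' depreciation carry the published point values; quantities the published
#' sources do not state (operator salaries, misc OpEx unit rates,
#' scaling-model coefficients, preprocessing efficiencies for beet, cassava
#' and EFB) are documented placeholders and are listed in the set's
#' `calibration_needed` field.
#'
#' Bread-waste collection price is a computed field: twice the palm-biomass
#' (EFB) collection cost, reflecting the smaller scale of aggregation at
#' commercial bakeries versus palm mills.
#'
#' @return An `assumption_set`: a named list of tibbles and scalar
#'   parameters. See [validate_assumption_set()] for the invariants it
#'   satisfies.
#' @examples
#' a <- default_assumption_set()
#' a$facilities_rate
#' subset(a$feedstock_prices, feedstock == "corn_stover")
#' @export
default_assumption_set <- function() {
  regions <- tibble::tibble(
    name = c("USA", "EU", "SEA"),
    operator_salary_usd_per_year = c(45000, 40000, 13000),
    salary_multiplier = 2.0,
    corporate_tax_rate = c(0.26, 0.24, 0.23)
  )

  feedstocks <- tibble::tibble(
    name = c("glucose", "glycerin", "corn_stover", "sugar_beet", "cassava",
             "bread_waste", "palm_efb"),
    category = c("direct_sugar", "direct_sugar", "lignocellulosic",
                 "simple_waste", "simple_waste", "simple_waste",
                 "lignocellulosic"),
    carbon_source = c("glucose", "glycerol", rep("glucose", 5)),
    preprocessing_cost_usd_per_mt = c(0, 0, 80.34, 45, 45, 38.10, 75),
    preprocessing_efficiency_g_per_g = c(1, 1, 0.38, 0.25, 0.25, 0.55, 0.55),
    yield_drag_fraction = c(0, 0, 0.03, 0.01, 0.01, 0.005, 0.03),
    capex_multiplier = c(0.86, 0.86, 1.00, 1.00, 0.93, 0.93, 1.00),
    availability_cap_l = c(NA, NA, NA, NA, NA, 4.5e6, NA)
  )

  efb_price <- 48.82
  feedstock_prices <- tibble::tibble(
    feedstock = c("glucose", "glucose", "glucose",
                  "glycerin", "glycerin", "glycerin",
                  "corn_stover", "sugar_beet", "cassava", "palm_efb",
                  "bread_waste", "bread_waste", "bread_waste"),
    region = c("USA", "EU", "SEA",
               "USA", "EU", "SEA",
               "USA", "EU", "SEA", "SEA",
               "USA", "EU", "SEA"),
    price_usd_per_mt = c(500, 500, 400,
                         600, 600, 500,
                         42.50, 52.70, 29.01, efb_price,
                         rep(2 * efb_price, 3))
  )

  products <- tibble::tibble(
    name = c("crude_palm_oil", "high_oleic_oil", "low_ci_biofuel_oil",
             "lauric_acid_75"),
    cost_adjustment_factor = c(1.0, 1.0161, 0.9996, 1.0715)
  )

  product_prices <- tidyr::expand_grid(
    product = products$name, region = regions$name
  )
  flat <- c(crude_palm_oil = 875, high_oleic_oil = 1006, lauric_acid_75 = 1120)
  product_prices$price_usd_per_mt <- ifelse(
    product_prices$product == "low_ci_biofuel_oil",
    c(USA = 1389, EU = 1307, SEA = 1295)[product_prices$region],
    flat[product_prices$product]
  )

  scenarios <- tibble::tibble(
    scenario = rep(c("Current Tech Low", "Current Tech Base Case",
                     "Current Tech High", "Future Tech High"), each = 2),
    carbon_source = rep(c("glucose", "glycerol"), 4),
    titer_g_per_l = c(32.7, 7.86, 57.85, 13.73, 98.6, 23.6, 111.63, 26.88),
    actual_yield_fraction = rep(c(0.50, 0.66, 0.77, 1.00), each = 2),
    theoretical_yield_g_per_g = rep(c(0.35, 0.38), 4)
  )

  new_assumption_set(list(
    schema_version = 1L,
    regions = regions,
    feedstocks = feedstocks,
    feedstock_prices = feedstock_prices,
    products = products,
    product_prices = product_prices,
    scenarios = scenarios,
    capex_model = new_scaling_model(log_intercept = log(344.6),
                                    exponent = 0.846),
    labor_model = new_scaling_model(log_intercept = log(0.0188),
                                    exponent = 0.525),
    misc_opex = list(
      media_usd_per_batch_l = 0.008,
      recovery_usd_per_kg_lipid = 0.15,
      consumables_usd_per_year = 60000,
      disposables_usd_per_year = 15000,
      waste_usd_per_mt_feedstock = 5.0
    ),
    facilities_rate = 0.050,
    other_rate = 0.169,
    depreciation_years = 20L,
    calibration_needed = c(
      "regions.operator_salary_usd_per_year",
      "feedstocks.preprocessing_efficiency_g_per_g[sugar_beet,cassava,palm_efb,bread_waste]",
      "feedstocks.preprocessing_cost_usd_per_mt[sugar_beet,cassava,palm_efb]",
      "feedstocks.yield_drag_fraction[sugar_beet,cassava,bread_waste]",
      "scenarios.actual_yield_fraction[current scenarios]",
      "capex_model", "labor_model", "misc_opex",
      "plant defaults: utilization 330 d, turnaround 1 d, recovery 0.95"
    )
  ))
}

#' Validate an assumption set
#'
#' Checks every type invariant of the data model and returns the violations
#' as data, not exceptions: positive salaries and prices, tax rates in
#' `[0, 1)`, feedstock categories from the closed set, preprocessing
#' identities for direct sugars (efficiency 1, zero preprocessing cost, zero
#' drag), yield drag capped at 3%, CapEx multipliers in `(0, 1]`, titers and
#' yield fractions in range, referential integrity of the price tables
#' against the declared regions and feedstocks, rates in `[0, 1]`, and a
#' positive depreciation horizon.
#'
#' @param a An `assumption_set`.
#' @return Character vector of violation descriptions, each naming the type,
#'   field, and rule; `character(0)` if the set is valid.
#' @examples
#' validate_assumption_set(default_assumption_set())
#' @export
validate_assumption_set <- function(a) {
  v <- character()
  say <- function(...) v <<- c(v, paste0(...))

  r <- a$regions
  if (any(r$operator_salary_usd_per_year <= 0))
    say("RegionProfile.operator_salary_usd_per_year: must be > 0")
  if (any(r$corporate_tax_rate < 0 | r$corporate_tax_rate >= 1))
    say("RegionProfile.corporate_tax_rate: must be in [0, 1)")
  if (any(r$salary_multiplier < 1))
    say("RegionProfile.salary_multiplier: must be >= 1")

  f <- a$feedstocks
  if (!all(f$category %in% FEEDSTOCK_CATEGORIES))
    say("FeedstockProfile.category: must be one of ",
        paste(FEEDSTOCK_CATEGORIES, collapse = ", "))
  ds <- f$category == "direct_sugar"
  if (any(f$preprocessing_efficiency_g_per_g[ds] != 1))
    say("FeedstockProfile.preprocessing_efficiency_g_per_g: direct sugars must be exactly 1")
  if (any(f$preprocessing_cost_usd_per_mt[ds] != 0))
    say("FeedstockProfile.preprocessing_cost_usd_per_mt: direct sugars must be 0")
  if (any(f$yield_drag_fraction[ds] != 0))
    say("FeedstockProfile.yield_drag_fraction: direct sugars must be 0")
  if (any(f$preprocessing_efficiency_g_per_g <= 0 |
          f$preprocessing_efficiency_g_per_g > 1))
    say("FeedstockProfile.preprocessing_efficiency_g_per_g: must be in (0, 1]")
  if (any(f$yield_drag_fraction < 0 | f$yield_drag_fraction > 0.03))
    say("FeedstockProfile.yield_drag_fraction: must be in [0, 0.03] (3% cap)")
  if (any(f$capex_multiplier <= 0 | f$capex_multiplier > 1))
    say("FeedstockProfile.capex_multiplier: must be in (0, 1]")
  cap <- f$availability_cap_l
  if (any(!is.na(cap) & cap <= 0))
    say("FeedstockProfile.availability_cap_l: must be positive when present")

  fp <- a$feedstock_prices
  if (any(fp$price_usd_per_mt <= 0))
    say("FeedstockProfile.price_usd_per_mt: must be > 0")
  if (!all(fp$region %in% r$name))
    say("FeedstockProfile.regions_available: price table references undeclared region")
  if (!all(fp$feedstock %in% f$name))
    say("FeedstockProfile.price_usd_per_mt: price table references undeclared feedstock")

  p <- a$products
  if (any(p$cost_adjustment_factor < 0))
    say("ProductProfile.cost_adjustment_factor: must be >= 0")
  pp <- a$product_prices
  if (any(pp$price_usd_per_mt <= 0))
    say("ProductProfile.commodity_price_usd_per_mt: must be > 0")
  if (!all(pp$product %in% p$name))
    say("ProductProfile.commodity_price_usd_per_mt: price table references undeclared product")
  if (!all(pp$region %in% r$name))
    say("ProductProfile.commodity_price_usd_per_mt: price table references undeclared region")

  s <- a$scenarios
  if (any(s$titer_g_per_l <= 0))
    say("ProductivityScenario.titer_g_per_l: must be > 0")
  if (any(s$actual_yield_fraction <= 0 | s$actual_yield_fraction > 1))
    say("ProductivityScenario.actual_yield_fraction: must be in (0, 1]")
  if (any(s$theoretical_yield_g_per_g <= 0))
    say("ProductivityScenario.theoretical_yield_g_per_g: must be > 0")

  for (nm in c("capex_model", "labor_model")) {
    m <- a[[nm]]
    if (!inherits(m, "scaling_model"))
      say("AssumptionSet.", nm, ": must be a scaling_model")
  }
  mo <- a$misc_opex
  if (!setequal(names(mo), MISC_OPEX_KEYS)) {
    say("MiscOpexRates: keys must be exactly {",
        paste(MISC_OPEX_KEYS, collapse = ", "), "}")
  } else if (any(unlist(mo) < 0)) {
    say("MiscOpexRates: all unit costs must be >= 0")
  }
  for (nm in c("facilities_rate", "other_rate")) {
    if (a[[nm]] < 0 || a[[nm]] > 1)
      say("AssumptionSet.", nm, ": must be in [0, 1]")
  }
  if (a$depreciation_years <= 0)
    say("AssumptionSet.depreciation_years: must be > 0")

  v
}

stop_if_invalid <- function(a) {
  v <- validate_assumption_set(a)
  if (length(v) > 0) {
    abort(c("Assumption set failed validation:", setNames(v, rep("x", length(v)))),
          class = "oleotea_validation_error")
  }
  invisible(a)
}

#' Write an assumption set to a YAML config file
#'
#' Serializes in a canonical, diff-stable key order. Tables are written as
#' row records so the file stays human-editable. [load_assumption_set()]
#' round-trips the output to an identical set.
#'
#' @param a An `assumption_set`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_assumption_set <- function(a, path) {
  ser <- lapply(unclass(a)[ASSUMPTION_KEYS], function(x) {
    if (inherits(x, "scaling_model")) unclass(x)
    else if (is.data.frame(x)) purrr::transpose(as.list(as.data.frame(x)))
    else x
  })
  yaml::write_yaml(ser, path, column.major = FALSE)
  invisible(path)
}

#' Load and validate an assumption set from a YAML config file
#'
#' Rejects unknown top-level keys, rebuilds the tables, and runs the full
#' validator; a schema violation raises an error naming the offending field.
#' Per-carbon-source sparsity in `scenarios` is permitted (a scenario may
#' define a titer for glucose only).
#'
#' @param path Path to a YAML file written by [write_assumption_set()] (or
#'   hand-edited in the same schema).
#' @return A validated `assumption_set`.
#' @export
load_assumption_set <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "oleotea_io_error")
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort(
      paste0("Failed to parse config '", path, "': ", conditionMessage(e)),
      class = "oleotea_format_error")
  )
  unknown <- setdiff(names(raw), ASSUMPTION_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "oleotea_validation_error")
  }
  missing <- setdiff(ASSUMPTION_KEYS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Config missing required keys: ",
                 paste(missing, collapse = ", ")),
          class = "oleotea_validation_error")
  }
  rebuild_tbl <- function(rows) {
    dplyr::bind_rows(lapply(rows, function(row) {
      tibble::as_tibble(lapply(row, function(x) if (is.null(x)) NA else x))
    }))
  }
  a <- raw
  for (nm in c("regions", "feedstocks", "feedstock_prices", "products",
               "product_prices", "scenarios")) {
    a[[nm]] <- rebuild_tbl(raw[[nm]])
  }
  for (nm in c("capex_model", "labor_model")) {
    m <- raw[[nm]]
    a[[nm]] <- new_scaling_model(
      log_intercept = m$log_intercept, exponent = m$exponent,
      r_squared = m$r_squared %||% NA_real_,
      n_points = m$n_points %||% NA_integer_
    )
  }
  a$schema_version <- as.integer(a$schema_version)
  a$depreciation_years <- as.integer(a$depreciation_years)
  a$calibration_needed <- as.character(unlist(a$calibration_needed))
  a <- new_assumption_set(a)
  stop_if_invalid(a)
  a
}

#' @export
print.assumption_set <- function(x, ...) {
  cat("<assumption_set> schema_version", x$schema_version, "\n")
  cat("  regions:    ", paste(x$regions$name, collapse = ", "), "\n")
  cat("  feedstocks: ", paste(x$feedstocks$name, collapse = ", "), "\n")
  cat("  products:   ", paste(x$products$name, collapse = ", "), "\n")
  cat("  scenarios:  ", paste(unique(x$scenarios$scenario), collapse = "; "), "\n")
  cat("  facilities_rate", x$facilities_rate,
      "| other_rate", x$other_rate,
      "| depreciation_years", x$depreciation_years, "\n")
  invisible(x)
}

# Lookup helpers used across the engine; base subsetting for speed in sweeps.

lookup_region <- function(a, region) {
  i <- match(region, a$regions$name)
  if (is.na(i)) {
    abort(paste0("Unknown region: ", region), class = "oleotea_validation_error")
  }
  a$regions[i, ]
}

lookup_feedstock <- function(a, feedstock) {
  i <- match(feedstock, a$feedstocks$name)
  if (is.na(i)) {
    abort(paste0("Unknown feedstock: ", feedstock),
          class = "oleotea_validation_error")
  }
  a$feedstocks[i, ]
}

feedstock_price <- function(a, feedstock, region) {
  fp <- a$feedstock_prices
  i <- which(fp$feedstock == feedstock & fp$region == region)
  if (length(i) == 0) {
    abort(paste0("Feedstock '", feedstock, "' is not available in region '",
                 region, "'"), class = "oleotea_availability_error")
  }
  fp$price_usd_per_mt[i[1]]
}

lookup_scenario <- function(a, scenario, carbon_source) {
  s <- a$scenarios
  i <- which(s$scenario == scenario & s$carbon_source == carbon_source)
  if (length(i) == 0) {
    abort(paste0("Scenario '", scenario, "' has no titer for carbon source '",
                 carbon_source, "'"), class = "oleotea_missing_feed_error")
  }
  s[i[1], ]
}

lookup_product <- function(a, product, region) {
  i <- match(product, a$products$name)
  if (is.na(i)) {
    abort(paste0("Unknown product: ", product),
          class = "oleotea_validation_error")
  }
  pp <- a$product_prices
  j <- which(pp$product == product & pp$region == region)
  if (length(j) == 0) {
    abort(paste0("No price for product '", product, "' in region '", region, "'"),
          class = "oleotea_validation_error")
  }
  list(name = product,
       cost_adjustment_factor = a$products$cost_adjustment_factor[i],
       price_usd_per_mt = pp$price_usd_per_mt[j[1]])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
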
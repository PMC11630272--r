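test_that("a single run composes the full model deterministically", {
  a <- DEFAULTS
  r <- run_scenario(a, base_plant(), "Current Tech Base Case",
                    "crude_palm_oil")
  expect_s3_class(r, "scenario_result")
  expect_gt(r$breakdown$components[["preprocessing"]], 0)
  expect_named(r$breakdown$components, cost_components())
  top2 <- names(sort(r$breakdown$components, decreasing = TRUE))[1:2]
  expect_true(all(top2 %in% cost_components()))

  # glucose plant: preprocessing is exactly zero
  rg <- run_scenario(a, plant_spec(1.5e7, "USA", "glucose"),
                     "Current Tech Base Case", "crude_palm_oil")
  expect_identical(rg$breakdown$components[["preprocessing"]], 0)

  # determinism: identical inputs, identical serialized results
  r2 <- run_scenario(a, base_plant(), "Current Tech Base Case",
                     "crude_palm_oil")
  expect_identical(serialize(r, NULL), serialize(r2, NULL))

  expect_error(run_scenario(a, plant_spec(1e6, "Mars", "glucose"),
                            "Current Tech Base Case", "crude_palm_oil"),
               class = "oleotea_validation_error")
})

test_that("capacity above a feedstock availability cap flags, not errors", {
  r <- run_scenario(DEFAULTS, plant_spec(1e7, "EU", "bread_waste"),
                    "Current Tech Base Case", "crude_palm_oil")
  expect_match(r$flags, "availability_cap_exceeded", all = FALSE)
  r_ok <- run_scenario(DEFAULTS, plant_spec(4.5e6, "EU", "bread_waste"),
                       "Current Tech Base Case", "crude_palm_oil")
  expect_length(r_ok$flags, 0)
})

test_that("product adjustment scales costs by a few percent, prices differ", {
  a <- DEFAULTS
  cpo <- run_scenario(a, base_plant(), "Current Tech Base Case",
                      "crude_palm_oil")
  lauric <- run_scenario(a, base_plant(), "Current Tech Base Case",
                         "lauric_acid_75")
  expect_equal(lauric$cogs_usd_per_kg / cpo$cogs_usd_per_kg, 1.0715)
  expect_equal(lauric$price_usd_per_mt, 1120)
  # low-CI oil price is region-keyed
  usa <- run_scenario(a, plant_spec(1.5e7, "USA", "glucose"),
                      "Current Tech Base Case", "low_ci_biofuel_oil")
  expect_equal(usa$price_usd_per_mt, 1389)
})

test_that("grid sweep excludes infeasible cells and orders canonically", {
  a <- DEFAULTS
  res <- sweep_scenarios(a)
  # availability filter: no cassava outside SEA, no bread waste above 4.5M L
  expect_false(any(res$feedstock == "cassava" & res$region != "SEA"))
  expect_false(any(res$feedstock == "bread_waste" & res$capacity_l > 4.5e6))
  inf <- attr(res, "infeasible")
  expect_gt(nrow(inf), 0)
  expect_setequal(unique(inf$reason),
                  c("feedstock_not_available_in_region",
                    "capacity_exceeds_availability_cap"))
  expect_equal(nrow(res) + nrow(inf),
               7 * 3 * 7 * 4 * 4 * 2)

  # 1x1x...x1 grid gives exactly one result
  tiny <- list(capacities_l = 1.5e6, regions = "SEA", feedstocks = "cassava",
               scenarios = "Current Tech Base Case",
               products = "crude_palm_oil", modes = "batch")
  expect_equal(nrow(sweep_scenarios(a, tiny)), 1)

  # shuffled axis input order yields identical output ordering
  shuffled <- default_grid(a)
  shuffled$feedstocks <- rev(shuffled$feedstocks)
  shuffled$capacities_l <- withr::with_seed(2, sample(shuffled$capacities_l))
  res2 <- sweep_scenarios(a, shuffled)
  expect_equal(res2[names(res2) != "breakdown"],
               res[names(res) != "breakdown"],
               ignore_attr = TRUE)
})

test_that("breakdown reports show shares summing to 100 and round-trip", {
  r <- run_scenario(DEFAULTS, base_plant(), "Current Tech Base Case",
                    "crude_palm_oil")
  rep <- breakdown_report(r)
  expect_equal(sum(rep$share_pct), 100, tolerance = 0.05)
  expect_equal(sum(rep$usd_per_kg), r$cogs_usd_per_kg, tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rep, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(rep))
})

test_that("sweep results serialize to a stable delimited table", {
  a <- DEFAULTS
  tiny <- list(capacities_l = c(5e4, 1.5e7), regions = "SEA",
               feedstocks = c("glucose", "palm_efb"),
               scenarios = "Current Tech Base Case",
               products = "crude_palm_oil", modes = "batch")
  res <- sweep_scenarios(a, tiny)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(res))
  expect_true(all(c("region", "feedstock", "capacity_l", "scenario",
                    "product", "mode", "cogs_usd_per_kg",
                    "gross_margin_pct") %in% names(back)))
  expect_equal(back$cogs_usd_per_kg, res$cogs_usd_per_kg)
})

test_that("economy of scale: COGS/kg non-increasing along the capacity ladder", {
  a <- DEFAULTS
  grid <- default_grid(a)
  grid$modes <- "batch"
  grid$products <- "crude_palm_oil"
  res <- sweep_scenarios(a, grid)
  by_curve <- split(res, list(res$region, res$feedstock, res$scenario),
                    drop = TRUE)
  for (curve in by_curve) {
    curve <- curve[order(curve$capacity_l), ]
    expect_true(all(diff(curve$cogs_usd_per_kg) <= 1e-12),
                info = paste(curve$region[1], curve$feedstock[1],
                             curve$scenario[1]))
  }
})

test_that("cheaper glucose-equivalents make waste streams beat glucose", {
  a <- DEFAULTS
  f <- a$feedstocks
  for (region in a$regions$name) {
    glu_price <- a$feedstock_prices
    glu <- glu_price$price_usd_per_mt[glu_price$feedstock == "glucose" &
                                        glu_price$region == region]
    wastes <- glu_price$feedstock[glu_price$region == region]
    wastes <- setdiff(wastes, c("glucose", "glycerin"))
    for (w in wastes) {
      row <- f[f$name == w, ]
      price <- glu_price$price_usd_per_mt[glu_price$feedstock == w &
                                            glu_price$region == region]
      per_glucose <- (price + row$preprocessing_cost_usd_per_mt) /
        row$preprocessing_efficiency_g_per_g
      if (per_glucose < glu * (1 - row$yield_drag_fraction)) {
        rw <- run_scenario(a, plant_spec(1.5e6, region, w),
                           "Current Tech Base Case", "crude_palm_oil")
        rg <- run_scenario(a, plant_spec(1.5e6, region, "glucose"),
                           "Current Tech Base Case", "crude_palm_oil")
        feed_cost <- function(r) {
          sum(r$breakdown$components[c("raw_material", "preprocessing")]) /
            (r$annual_output_mt * 1000)
        }
        expect_lt(feed_cost(rw), feed_cost(rg))
      }
    }
  }
})
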
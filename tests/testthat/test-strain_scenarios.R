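test_that("per-strain summaries average the literature table correctly", {
  tab <- read_strain_table()
  expect_equal(nrow(tab), 36)

  s <- summarize_by_strain(tab)
  rt <- s[s$strain == "R. toruloides", ]
  expect_equal(rt$mean_titer, (67.5 + 78.7) / 2) # = 73.1
  expect_equal(rt$n_records, 2L)

  # single-record strain: summary equals the record
  cc <- s[s$strain == "C. curvatus", ]
  expect_equal(cc$mean_titer, 86.1)
  expect_equal(cc$mean_yield, 0.25)
  expect_equal(cc$n_records, 1L)

  # missing values excluded, not imputed: all L. starkeyi yields are N/A
  ls <- s[s$strain == "L. starkeyi", ]
  expect_true(is.na(ls$mean_yield))
  expect_equal(ls$mean_titer, 17.58)

  expect_error(summarize_by_strain(tab[0, ]),
               class = "oleotea_empty_input_error")
})

test_that("summaries match a brute-force loop oracle and ignore row order", {
  spec <- synthetic_spec(seed = 42L, n_strains = 10L, records_per_strain = 20L)
  tab <- gen_strain_table(spec)
  expect_equal(nrow(tab), 200)

  got <- summarize_by_strain(tab)
  want <- summarize_oracle(tab)
  expect_equal(got$strain, want$strain)
  expect_equal(got$mean_titer, want$mean_titer)
  expect_equal(got$mean_productivity, want$mean_productivity)
  expect_equal(got$mean_yield, want$mean_yield)
  expect_equal(got$n_records, want$n_records)

  shuffled <- tab[withr::with_seed(7, sample(nrow(tab))), ]
  expect_equal(summarize_by_strain(shuffled), got)
})

test_that("percent of theoretical yield is the plain ratio, bounded by 1", {
  expect_equal(percent_theoretical_yield(0.35, "glucose"), 1.0)
  expect_equal(percent_theoretical_yield(0.27, "glucose"), 0.27 / 0.35)
  expect_equal(percent_theoretical_yield(0.33, "glycerol"), 0.33 / 0.38)
  expect_error(percent_theoretical_yield(0.40, "glucose"),
               class = "oleotea_out_of_range_error")
  expect_error(percent_theoretical_yield(0.3, "sucrose"),
               class = "oleotea_missing_feed_error")
})

test_that("authors_published returns the published scenario titers", {
  s <- derive_productivity_scenarios(subset_rule = "authors_published")
  titer <- function(sc, cs) s$titer_g_per_l[s$scenario == sc &
                                              s$carbon_source == cs]
  expect_equal(titer("Current Tech High", "glucose"), 98.6)
  expect_equal(titer("Current Tech Base Case", "glucose"), 57.85)
  expect_equal(titer("Current Tech Low", "glucose"), 32.7)
  expect_equal(titer("Future Tech High", "glucose"), 111.63)
  expect_equal(titer("Current Tech High", "glycerol"), 23.6)
  expect_equal(titer("Current Tech Base Case", "glycerol"), 13.73)
  expect_equal(titer("Current Tech Low", "glycerol"), 7.86)
  expect_equal(titer("Future Tech High", "glycerol"), 26.88)
  expect_equal(s$theoretical_yield_g_per_g,
               ifelse(s$carbon_source == "glucose", 0.35, 0.38))
})

test_that("computed rule matches sort-based quantile and mean oracles", {
  spec <- synthetic_spec(seed = 11L, n_strains = 50L, records_per_strain = 10L)
  tab <- gen_strain_table(spec, missing_fraction = 0)
  s <- derive_productivity_scenarios(tab, subset_rule = "computed")
  for (fd in c("glucose", "glycerol")) {
    titers <- tab$titer_g_per_l[tab$feed == fd]
    pick <- function(sc) s$titer_g_per_l[s$scenario == sc &
                                           s$carbon_source == fd]
    expect_equal(pick("Current Tech Low"), mean(titers))
    expect_equal(pick("Current Tech Base Case"), quantile_oracle(titers, 0.75))
    expect_equal(pick("Current Tech High"), max(titers))
    # future rule: High scaled by the reciprocal of the best yield fraction
    best_frac <- max(tab$yield_g_per_g[tab$feed == fd] /
                       theoretical_yields()[[fd]])
    expect_equal(pick("Future Tech High"), max(titers) / best_frac)
  }
  expect_error(
    derive_productivity_scenarios(tab[tab$feed == "glucose", ],
                                  subset_rule = "computed"),
    class = "oleotea_missing_feed_error")
})

test_that("degenerate single-record input collapses all current scenarios", {
  one <- tibble::tibble(strain = "S", titer_g_per_l = 40,
                        productivity_g_per_l_per_hr = 0.4,
                        yield_g_per_g = 0.28, feed = "glucose", source = "x")
  s <- derive_productivity_scenarios(one, subset_rule = "computed",
                                     feeds = "glucose")
  cur <- s$titer_g_per_l[s$scenario != "Future Tech High"]
  expect_equal(cur, rep(40, 3))
  expect_equal(s$titer_g_per_l[s$scenario == "Future Tech High"],
               40 * 0.35 / 0.28)
})

test_that("scenario titers obey Low <= Base <= High <= Future across seeds", {
  for (seed in 1:10) {
    tab <- gen_strain_table(synthetic_spec(seed = seed, n_strains = 12L,
                                           records_per_strain = 6L))
    s <- derive_productivity_scenarios(tab, subset_rule = "computed")
    for (fd in c("glucose", "glycerol")) {
      t <- s$titer_g_per_l[s$carbon_source == fd]
      expect_false(is.unsorted(t))
    }
  }
  s <- derive_productivity_scenarios(subset_rule = "authors_published")
  for (fd in c("glucose", "glycerol")) {
    expect_false(is.unsorted(s$titer_g_per_l[s$carbon_source == fd]))
  }
})

test_that("base-case quantile agrees with the sorted-list oracle for all short inputs", {
  withr::with_seed(99, {
    for (n in c(2:12, 25, 50)) {
      x <- runif(n, 5, 100)
      rec <- tibble::tibble(strain = "S", titer_g_per_l = x,
                            productivity_g_per_l_per_hr = NA_real_,
                            yield_g_per_g = NA_real_, feed = "glucose",
                            source = "x")
      s <- derive_productivity_scenarios(rec, subset_rule = "computed",
                                         feeds = "glucose")
      got <- s$titer_g_per_l[s$scenario == "Current Tech Base Case"]
      expect_equal(got, quantile_oracle(x, 0.75))
    }
  })
})
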
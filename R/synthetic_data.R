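# Seeded generators for every input the pipeline consumes, with known
# ground truth: plant-build tables (a log-log linear capacity-CapEx cloud
# standing in for the external 2G-ethanol build dataset), strain tables with
# known population quantiles, and perturbed assumption sets. Each artifact
# type draws from its own seeded stream (a fixed offset from the spec seed),
# so adding one generator never perturbs another's output.

SEED_OFFSETS <- c(builds = 1L, strains = 2L, assumptions = 3L)

#' Specify a synthetic-data generation run
#'
#' @param seed Integer master seed; a fixed seed makes every generator's
#'   output byte-identical across calls.
#' @param n_builds Number of plant-build records.
#' @param capex_intercept,capex_exponent Power-law ground truth for CapEx vs
#'   capacity; defaults match the packaged CapEx model.
#' @param noise_sd_log Lognormal noise scale on CapEx (standard deviation of
#'   the log residual), >= 0.
#' @param n_strains,records_per_strain Strain-table dimensions.
#' @param titer_family Titer distribution: `"lognormal"` (`meanlog`, `sdlog`),
#'   `"uniform"` (`min`, `max`), or `"point"` (`value`).
#' @param titer_params Named list of the family's parameters.
#' @param assumption_perturbation Relative half-width of the multiplicative
#'   perturbation applied to each cost input by [gen_assumption_set()], in
#'   `[0, 1)`.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_builds = 40L,
                           capex_intercept = 344.6,
                           capex_exponent = 0.846,
                           noise_sd_log = 0.15,
                           n_strains = 10L,
                           records_per_strain = 5L,
                           titer_family = c("lognormal", "uniform", "point"),
                           titer_params = list(meanlog = 3.2, sdlog = 0.8),
                           assumption_perturbation = 0.1) {
  titer_family <- match.arg(titer_family)
  stopifnot(noise_sd_log >= 0, n_builds >= 2, n_strains >= 1,
            records_per_strain >= 1,
            assumption_perturbation >= 0, assumption_perturbation < 1)
  structure(
    list(seed = as.integer(seed), n_builds = as.integer(n_builds),
         capex_intercept = capex_intercept, capex_exponent = capex_exponent,
         noise_sd_log = noise_sd_log, n_strains = as.integer(n_strains),
         records_per_strain = as.integer(records_per_strain),
         titer_family = titer_family, titer_params = titer_params,
         assumption_perturbation = assumption_perturbation),
    class = "synthetic_spec"
  )
}

draw_titers <- function(n, family, p) {
  switch(family,
         lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
         uniform = runif(n, p$min, p$max),
         point = rep(p$value, n))
}

#' Generate synthetic plant-build records
#'
#' Capacities are log-uniform over the modeled 50k-15M L range; CapEx is
#' `intercept * capacity^exponent * exp(e)` with `e ~ Normal(0,
#' noise_sd_log)`. With zero noise, [fit_scaling_model()] recovers the
#' generating parameters exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble of build records (`capacity_l`, `capex_usd`, `region`).
#' @export
gen_build_records <- function(spec) {
  withr::with_seed(spec$seed + SEED_OFFSETS[["builds"]], {
    cap <- exp(runif(spec$n_builds, log(CAPACITY_RANGE_L[1]),
                     log(CAPACITY_RANGE_L[2])))
    eps <- rnorm(spec$n_builds, 0, spec$noise_sd_log)
    tibble::tibble(
      capacity_l = cap,
      capex_usd = spec$capex_intercept * cap^spec$capex_exponent * exp(eps),
      region = sample(c("USA", "EU", "SEA"), spec$n_builds, replace = TRUE)
    )
  })
}

#' Generate a synthetic strain-performance table
#'
#' Titers come from the spec's named family (known population quantiles);
#' yields are uniform on `(0, theoretical max]` for the record's feed, so
#' they never exceed stoichiometry; feeds alternate glucose/glycerol by
#' strain. `missing_fraction` injects an `NA` pattern into productivity and
#' yield, mimicking sparsely reported studies.
#'
#' @param spec A [synthetic_spec()].
#' @param missing_fraction Fraction of productivity/yield entries set `NA`.
#' @return Tibble in [read_strain_table()] format.
#' @export
gen_strain_table <- function(spec, missing_fraction = 0.2) {
  theo <- theoretical_yields()
  withr::with_seed(spec$seed + SEED_OFFSETS[["strains"]], {
    n <- spec$n_strains * spec$records_per_strain
    strain <- rep(sprintf("Strain_%02d", seq_len(spec$n_strains)),
                  each = spec$records_per_strain)
    feed <- rep(rep(c("glucose", "glycerol"),
                    length.out = spec$n_strains),
                each = spec$records_per_strain)
    titer <- draw_titers(n, spec$titer_family, spec$titer_params)
    yield <- runif(n, 0.01, 1) * theo[feed]
    prod <- titer / runif(n, 80, 200) # plausible g/L/hr given a 100-200 h run
    na_mask <- runif(n) < missing_fraction
    yield[na_mask] <- NA_real_
    prod[runif(n) < missing_fraction] <- NA_real_
    tibble::tibble(
      strain = strain,
      titer_g_per_l = titer,
      productivity_g_per_l_per_hr = prod,
      yield_g_per_g = unname(yield),
      feed = feed,
      source = paste0("synthetic_", seq_len(n))
    )
  })
}

#' Generate a perturbed assumption set
#'
#' Starts from [default_assumption_set()] and multiplies each cost input
#' (feedstock prices, preprocessing costs, salaries, misc OpEx rates) by an
#' independent factor drawn uniformly from
#' `[1 - assumption_perturbation, 1 + assumption_perturbation]`. Structural
#' fields (efficiencies, drags, rates, scaling exponents) are left alone so
#' the set always passes validation. Zero perturbation returns the default
#' set unchanged.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `assumption_set`.
#' @export
gen_assumption_set <- function(spec) {
  a <- default_assumption_set()
  p <- spec$assumption_perturbation
  if (p == 0) return(a)
  withr::with_seed(spec$seed + SEED_OFFSETS[["assumptions"]], {
    jitter <- function(x) x * runif(length(x), 1 - p, 1 + p)
    a$feedstock_prices$price_usd_per_mt <-
      jitter(a$feedstock_prices$price_usd_per_mt)
    a$feedstocks$preprocessing_cost_usd_per_mt <-
      jitter(a$feedstocks$preprocessing_cost_usd_per_mt)
    a$regions$operator_salary_usd_per_year <-
      jitter(a$regions$operator_salary_usd_per_year)
    a$misc_opex <- lapply(a$misc_opex, jitter)
  })
  stop_if_invalid(a)
  a
}
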
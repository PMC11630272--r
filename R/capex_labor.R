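# Capacity scaling of capital expense and staffing.
#
# Both CapEx and FTE headcount are modeled as power laws of fermentation
# capacity, fitted by ordinary least squares on the log-log scale, the
# standard cost-scaling treatment for process plants. Feedstock-specific
# CapEx multipliers reflect how much preprocessing equipment the plant
# needs: plants fed directly with glucose/glycerol drop preprocessing
# entirely (-14% total CapEx), simple-waste plants (cassava, bread waste)
# need only grinding/blending/centrifugation and capture half of that
# saving (-7%), and lignocellulosic plants keep the full pretreatment and
# enzymatic-hydrolysis train.

new_scaling_model <- function(log_intercept, exponent, r_squared = NA_real_,
                              n_points = NA_integer_) {
  structure(
    list(log_intercept = as.numeric(log_intercept),
         exponent = as.numeric(exponent),
         r_squared = as.numeric(r_squared),
         n_points = as.integer(n_points)),
    class = "scaling_model"
  )
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf(
    "<scaling_model> value = %.4g * capacity^%.4g  (R2 = %s, n = %s)\n",
    exp(x$log_intercept), x$exponent,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
    ifelse(is.na(x$n_points), "NA", x$n_points)))
  invisible(x)
}

#' Fit a power-law scaling model of cost (or staffing) vs capacity
#'
#' Ordinary least squares of `log(value)` on `log(capacity)`, i.e. the
#' power law `value = exp(log_intercept) * capacity^exponent`. The
#' coefficient of determination is reported on the log scale, the fit's
#' residual space.
#'
#' @param builds Data frame with a `capacity_l` column and the response
#'   column (default `capex_usd`); both must be positive.
#' @param value_col Name of the response column (`"capex_usd"` for plant
#'   builds, `"ftes"` for staffing tables).
#' @return A `scaling_model` with `log_intercept`, `exponent`, `r_squared`,
#'   and `n_points`.
#' @examples
#' builds <- tibble::tibble(capacity_l = c(1e5, 1e6, 1e7),
#'                          capex_usd = 3 * c(1e5, 1e6, 1e7)^0.62)
#' fit_scaling_model(builds)
#' @export
fit_scaling_model <- function(builds, value_col = "capex_usd") {
  if (!all(c("capacity_l", value_col) %in% names(builds))) {
    abort(paste0("builds must have columns capacity_l and ", value_col),
          class = "oleotea_validation_error")
  }
  cap <- builds$capacity_l
  val <- builds[[value_col]]
  keep <- !is.na(cap) & !is.na(val)
  cap <- cap[keep]; val <- val[keep]
  if (any(cap <= 0) || any(val <= 0)) {
    abort("capacities and values must be positive for a log-log fit",
          class = "oleotea_validation_error")
  }
  if (length(unique(cap)) < 2) {
    abort("need at least 2 records with distinct capacities to fit",
          class = "oleotea_degenerate_fit_error")
  }
  x <- log(cap); y <- log(val)
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1.0 else 1 - ss_res / ss_tot
  new_scaling_model(
    log_intercept = unname(coef(fit)[1]),
    exponent = unname(coef(fit)[2]),
    r_squared = r2,
    n_points = length(cap)
  )
}

predict_scaling <- function(model, capacity_l) {
  if (!inherits(model, "scaling_model")) {
    abort("model must be a fitted scaling_model", class = "oleotea_state_error")
  }
  exp(model$log_intercept) * capacity_l^model$exponent
}

#' Predict plant capital expense
#'
#' Applies the fitted capacity power law, then the feedstock's CapEx
#' multiplier (0.86 for direct sugars, 0.93 for simple wastes, 1.00 for
#' lignocellulosic feedstocks). Capacities outside the modeled 50k-15M L
#' range are extrapolations: a warning is emitted, not an error.
#'
#' @param model A `scaling_model` for CapEx vs capacity.
#' @param plant A [plant_spec()].
#' @param feedstock One-row feedstock tibble (from an assumption set's
#'   `feedstocks` table), or `NULL` for the unadjusted base prediction.
#' @return Capital expense in USD.
#' @export
predict_capex <- function(model, plant, feedstock = NULL) {
  cap <- plant$fermentation_capacity_l
  if (cap < CAPACITY_RANGE_L[1] || cap > CAPACITY_RANGE_L[2]) {
    warn(sprintf(
      "capacity %.3g L is outside the modeled range [%.0f, %.0f] L; CapEx prediction is an extrapolation",
      cap, CAPACITY_RANGE_L[1], CAPACITY_RANGE_L[2]),
      class = "oleotea_extrapolation_warning")
  }
  mult <- if (is.null(feedstock)) 1.0 else feedstock$capex_multiplier
  predict_scaling(model, cap) * mult
}

#' Straight-line annual depreciation
#'
#' @param capex_usd Capital expense (USD), positive.
#' @param years Depreciation horizon in years (default 20), positive.
#' @return Annual depreciation charge, USD/yr.
#' @export
annual_depreciation <- function(capex_usd, years = 20L) {
  if (capex_usd <= 0) {
    abort("capex_usd must be > 0", class = "oleotea_validation_error")
  }
  if (years <= 0) {
    abort("years must be > 0", class = "oleotea_validation_error")
  }
  capex_usd / years
}

#' Predict plant staffing from capacity
#'
#' Power-law prediction of full-time equivalents. Returned as a positive
#' real, not rounded: rounding introduces step artifacts in smooth scale
#' curves (use `round = TRUE` for reporting). A fitted exponent below 1
#' expresses the strong economy of scale of plant staffing.
#'
#' @param labor_model A `scaling_model` for FTEs vs capacity.
#' @param capacity_l Fermentation capacity in liters.
#' @param round Round to whole FTEs for display? Default `FALSE`.
#' @return FTE count (positive real).
#' @export
predict_ftes <- function(labor_model, capacity_l, round = FALSE) {
  ftes <- predict_scaling(labor_model, capacity_l)
  if (round) round(ftes) else ftes
}

#' Annual fully loaded labor cost
#'
#' Salary plus overhead per FTE is a multiple (default twice) of the
#' average machine-operator salary in the plant's region, reflecting the
#' skilled-technician premium.
#'
#' @param ftes FTE count, >= 0.
#' @param region One-row region tibble (from an assumption set's `regions`
#'   table).
#' @return Labor cost, USD/yr.
#' @export
annual_labor_cost <- function(ftes, region) {
  stopifnot(ftes >= 0)
  ftes * region$salary_multiplier * region$operator_salary_usd_per_year
}

#' Read a plant-build (or staffing) table from a delimited file
#'
#' Expected header: `capacity_l, capex_usd[, ftes, region]`.
#'
#' @param path CSV file path.
#' @return Tibble of build records.
#' @export
read_build_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA", "N/A"))
}
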
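# Aggregation of annual costs into COGS, cost shares, and margins.

#' Construct a cost breakdown
#'
#' @param components Named numeric vector or list of annual costs (USD/yr).
#'   Names must come from [cost_components()]; omitted components default
#'   to zero.
#' @param annual_output_mt Annual saleable output, MT/yr (> 0).
#' @return A `cost_breakdown`.
#' @export
cost_breakdown <- function(components, annual_output_mt) {
  components <- unlist(components)
  extra <- setdiff(names(components), COST_COMPONENTS)
  if (length(extra) > 0) {
    abort(paste0("Unknown cost components: ", paste(extra, collapse = ", "),
                 " (allowed: ", paste(COST_COMPONENTS, collapse = ", "), ")"),
          class = "oleotea_validation_error")
  }
  if (annual_output_mt <= 0) {
    abort("annual_output_mt must be > 0", class = "oleotea_validation_error")
  }
  full <- setNames(numeric(length(COST_COMPONENTS)), COST_COMPONENTS)
  full[names(components)] <- components
  if (any(full < 0)) {
    abort("cost components must be non-negative",
          class = "oleotea_validation_error")
  }
  structure(list(components = full, annual_output_mt = annual_output_mt),
            class = "cost_breakdown")
}

#' Cost of goods sold per kilogram
#'
#' Sum of all annual cost components divided by annual output in kg.
#'
#' @param b A [cost_breakdown()].
#' @return USD/kg.
#' @export
cogs_per_kg <- function(b) {
  if (b$annual_output_mt <= 0) {
    abort("annual output must be > 0", class = "oleotea_validation_error")
  }
  sum(b$components) / (b$annual_output_mt * 1000)
}

#' Cost shares by component
#'
#' Each component's fraction of total annual cost; fractions sum to 1.
#'
#' @param b A [cost_breakdown()].
#' @return Named numeric vector of fractions over the closed component set.
#' @export
cost_shares <- function(b) {
  total <- sum(b$components)
  if (total <= 0) {
    abort("cost shares are undefined when all components are zero",
          class = "oleotea_validation_error")
  }
  b$components / total
}

#' Gross margin percentage
#'
#' `(price - cogs) / price * 100`, both in USD/MT. Negative whenever
#' production cost exceeds the commodity price.
#'
#' @param price_usd_per_mt Commodity sales price, USD/MT (> 0).
#' @param cogs_usd_per_mt Production cost, USD/MT.
#' @return Gross margin in percent.
#' @examples
#' gross_margin_pct(875, 1469) # crude palm oil vs its best-case cost
#' @export
gross_margin_pct <- function(price_usd_per_mt, cogs_usd_per_mt) {
  if (price_usd_per_mt <= 0) {
    abort("price_usd_per_mt must be > 0", class = "oleotea_domain_error")
  }
  (price_usd_per_mt - cogs_usd_per_mt) / price_usd_per_mt * 100
}

#' Batch-to-continuous production-cost decrease
#'
#' Percent decrease in COGS/kg when switching a plant from batch to
#' continuous operation.
#'
#' @param batch_cogs Batch-mode COGS, USD/kg (> 0).
#' @param continuous_cogs Continuous-mode COGS, USD/kg.
#' @return Percent decrease (negative if continuous is more expensive).
#' @examples
#' mode_delta_pct(2.36, 2.25)
#' @export
mode_delta_pct <- function(batch_cogs, continuous_cogs) {
  stopifnot(batch_cogs > 0)
  (batch_cogs - continuous_cogs) / batch_cogs * 100
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown>", format(x$annual_output_mt, big.mark = ","),
      "MT/yr |", sprintf("$%.2f/kg", cogs_per_kg(x)), "\n")
  nz <- x$components[x$components > 0]
  shares <- nz / sum(x$components) * 100
  for (nm in names(sort(nz, decreasing = TRUE))) {
    cat(sprintf("  %-13s $%14s/yr  (%5.2f%%)\n", nm,
                format(round(nz[[nm]]), big.mark = ","), shares[[nm]]))
  }
  invisible(x)
}
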
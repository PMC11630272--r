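# Shared fixtures, built once per test run.

DEFAULTS <- default_assumption_set()

# brute-force quantile oracle: sort + linear interpolation between order
# statistics (inclusive convention), written independently of stats::quantile
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - (lo - 1)) * (x[hi] - x[lo])
}

# brute-force group-and-average oracle with explicit loops
summarize_oracle <- function(records) {
  strains <- sort(unique(records$strain))
  out <- data.frame(strain = strains, mean_titer = NA_real_,
                    mean_productivity = NA_real_, mean_yield = NA_real_,
                    n_records = NA_integer_)
  for (i in seq_along(strains)) {
    rows <- records[records$strain == strains[i], ]
    avg <- function(col) {
      v <- rows[[col]][!is.na(rows[[col]])]
      if (length(v) == 0) NA_real_ else sum(v) / length(v)
    }
    out$mean_titer[i] <- avg("titer_g_per_l")
    out$mean_productivity[i] <- avg("productivity_g_per_l_per_hr")
    out$mean_yield[i] <- avg("yield_g_per_g")
    out$n_records[i] <- nrow(rows)
  }
  out
}

base_plant <- function(capacity_l = 1.5e7, region = "SEA",
                       feedstock = "palm_efb", ...) {
  plant_spec(capacity_l, region, feedstock, ...)
}
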
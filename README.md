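# oleotea

A techno-economic scenario engine for microbial oil production by oleaginous
yeasts at industrial scale.

Microbial lipids are a candidate replacement for commodity plant oils (crude
palm oil, high-oleic cooking oil, biofuel feedstock oil, lauric acid), but
whether fermentation can ever reach price parity depends on how strain
productivity, plant scale, region, and feedstock interact. `oleotea`
implements a complete, deterministic cost model of that question, for
bioprocess economists, metabolic engineers sizing up commercialization, and
anyone who wants to stress-test "waste-stream valorization" claims with
explicit numbers.

## The model

One scenario is a tuple (region, feedstock, fermentation capacity,
productivity scenario, product, mode). The engine composes:

- **Productivity scenarios.** A titer *T* (g/L) and an actual-yield fraction
  *f* of the stoichiometric maximum *Y*<sub>theo</sub> (0.35 g lipid / g
  glucose, 0.38 g/g glycerol, to palmitic acid) per carbon source. Four named
  ladders span bench-scale reality to a theoretical best case: Current Tech
  Low / Base Case / High, and Future Tech High (100% of theoretical yield).
  They can be derived from a packaged 36-row literature table (mean, third
  quartile, maximum titer) or taken as published.
- **Mass balance.** Batch plants run
  `batches/yr = utilization / (fermentation + turnaround)` cycles; annual
  recovered lipid is `V · T · batches · recovery / 1e6` MT. Sugar demand
  inverts the yield chain `Y_theo · f · (1 − drag)`, and raw feedstock demand
  divides by the preprocessing efficiency (g glucose per g raw feedstock).
  Continuous plants produce at dilution rate *D* (default 0.14/d, about one
  media volume per week), which also normalizes media usage across modes.
- **Capacity scaling.** CapEx and staffing follow power laws
  `cost = c · V^b` fitted by log-log OLS to plant-build tables
  (second-generation ethanol plants are the construction-cost analog).
  Direct-sugar plants drop preprocessing equipment (−14% CapEx); simple
  wastes (cassava, bread waste) capture half that saving.
- **Operating costs.** Regional feedstock prices, preprocessing cost per
  tonne, labor at 2× the regional machine-operator salary, 20-year
  straight-line depreciation, facilities at 5.0% of CapEx, "other" at 16.9%
  of facilities, plus media/recovery/consumables/waste unit costs.
- **Economics.** COGS/kg = Σ components / output;
  `gross margin % = (price − COGS) / price × 100`.

## Worked example

The flagship configuration — 15M L (ten 1.5M-L reactors) in Southeast Asia
fed palm empty fruit bunches (EFB), base-case productivity, sold as a crude
palm oil alternative:

```r
library(oleotea)
a <- default_assumption_set()
plant <- plant_spec(15e6, "SEA", "palm_efb")
r <- run_scenario(a, plant, "Current Tech Base Case", "crude_palm_oil")
r
#> <scenario_result> SEA | palm_efb | 1.5e+07 L | batch | Current Tech Base Case | crude_palm_oil
#>   output 45340 MT/yr | COGS $2.43/kg | price $875/MT | gross margin -177.9%

breakdown_report(r)
#> # A tibble: 11 × 4
#>    component     usd_per_year usd_per_kg share_pct
#>  1 raw_material     18906393.   0.417        17.2
#>  2 preprocessing    29045053.   0.641        26.4
#>  3 media             6600000    0.146         5.99
#>  4 labor             2861404.   0.0631        2.6
#>  5 depreciation     20288899.   0.447        18.4
#>  6 facilities       20288899.   0.447        18.4
#>  7 recovery          6800991.   0.15          6.17
#>  8 consumables         60000    0.00132       0.05
#>  9 disposables         15000    0.000331      0.01
#> 10 waste             1936337.   0.0427        1.76
#> 11 other             3428824.   0.0756        3.11
```

The plant makes about 45,000 MT of oil a year at $2.43/kg — but crude palm
oil sells near $875/MT ($0.875/kg), so the gross margin is deeply negative:
cost, not demand, is the barrier. The breakdown shows why no single lever
fixes it: feedstock + preprocessing (~44%), capital + facilities (~37%), and
everything else are all material.

Sweeping the full default grid (7 capacities × 3 regions × 7 feedstocks × 4
productivity scenarios × 4 products × 2 modes, availability-filtered):

```r
res <- sweep_scenarios(a)
nrow(res)
#> [1] 2720
res[which.min(res$cogs_usd_per_kg),
    c("region", "feedstock", "scenario", "cogs_usd_per_kg")]
#>   region feedstock scenario         cogs_usd_per_kg
#> 1 SEA    palm_efb  Future Tech High        1.49
```

Even the cheapest corner of the grid — maximum scale, the cheapest waste
stream, and a strain at 100% of theoretical yield — stays above $1/kg.

## Acceptance script

`scripts/acceptance.R` re-derives the productivity scenarios from the
packaged literature table, fits the capacity power law on a seeded synthetic
build table, runs the full default sweep, and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Learn more

The methods vignette (`vignettes/methods.Rmd`) documents the model's
assumptions, every tunable parameter with units and defaults, which defaults
are placeholders pending plant-level calibration, what the synthetic-data
generators do and do not emulate, and known limitations.
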
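Package: oleotea
Title: Techno-Economic Scenario Engine for Microbial Oil Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A deterministic techno-economic model of lipid production by
    oleaginous yeasts at industrial scale. Converts strain productivity
    scenarios (titer, yield, recovery), plant capacity, region, feedstock,
    and end market into annual output, a cost-of-goods-sold breakdown, and
    gross margin. Capital expense and staffing are scaled with capacity by
    power laws fitted to second-generation ethanol plant builds; waste-stream
    feedstocks (corn stover, sugar beet, cassava, bread waste, palm empty
    fruit bunches) are costed through collection price, preprocessing
    efficiency and yield drag. Includes a literature strain-performance
    table, scenario-grid sweeps over thousands of configurations, and a
    seeded synthetic-data module so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
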
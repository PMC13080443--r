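Package: bioreach
Title: Reach and Coverage Estimation for Biofortified Staple Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A validated, configuration-driven calculation engine for estimating
    how many people (reach) and what share of a national population (coverage)
    consume biofortified staple crops, on-farm and off-farm. Implements a
    five-phase seed-to-consumption accounting chain (seed availability with
    farm-saved-seed back-calculation, crop production, on-farm consumption,
    off-farm consumption under replacement scenarios, and national reach and
    coverage), a seed-acquisition/diffusion/attrition model of the number of
    growing households, provenance-tagged parameter sets with schema validation,
    scenario and one-at-a-time sensitivity analysis, and table renderers for
    country-crop comparisons. Ships worked country-crop parameter sets for zinc
    rice (Bangladesh), zinc wheat (Pakistan), and vitamin A maize and cassava
    (Nigeria).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
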
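# bioreach

Reach and coverage estimation for biofortified staple crops.

Biofortification programs breed staple crops (zinc rice and wheat,
provitamin-A maize and cassava, ...) with higher micronutrient content.
The two indicators their managers and policymakers track are **reach** —
the number of people consuming the biofortified food in a year — and
**coverage** — reach as a percentage of the national population. Coverage
surveys struggle here: many biofortified crops have no visible trait, so
market consumers cannot report them reliably. `bioreach` implements the
accounting alternative: a deterministic five-phase seed-to-consumption
calculation driven by a small, provenance-tagged parameter set per
country-crop-year.

The five phases, with parameters keyed by accounting ID:

1. **Seed availability** — total seed used `1D = 1B×1C` (area × seed
   rate); farm-saved seed ratio `1F = max(0, (1D−1E)/1E)`; biofortified
   seed planted `1H = 1A×(1+1F)`.
2. **Production** — area `2B = 1H/2A`, harvest `2D = 2B×2C`, edible
   supply `2H = 2D×(1−2E−2F−2G)` after seed, feed and post-harvest-loss
   deductions.
3. **On-farm consumption** — farming population `3D = 3B×3C`, on-farm
   tonnage `3E = 3D×3A/1000`.
4. **Off-farm consumption** — market quantity `4A = 2H−3E`; under
   replacement fraction `r` (default scenarios `r = 1` and `r = 0.5`),
   off-farm population `4C = 1000·4A/(r·4B)`.
5. **Reach and coverage** — `5A = 3D + 4C`, `5C = 100·5A/5B`.

Everything is carried at full precision and rounded (half-up) only at
report time. Cassava planting material is counted in bundles of stems and
never converted to mass. Implausible results (reach above the national
population, intakes outside 100–600 g/day) are flagged, never silently
accepted. The number of growing households (`3B`) can be supplied
directly or modelled from seed sales with farmer-to-farmer diffusion and
attrition (`households_from_packs()`, `project_growers()`).

## Worked example

Four published country-crop parameter sets for 2023 ship with the
package:

```r
library(bioreach)

est <- estimate_reach(reach_fixture("bangladesh_zinc_rice_2023"))
est
#> <reach_estimate> Bangladesh rice (zinc), 2023
#>   farming population: 7,146,493
#>   full replacement:  reach 12,429,704 (coverage 7%)
#>   half replacement:  reach 17,712,914 (coverage 10%)
```

7.1 million people live in households growing zinc rice; depending on
whether market consumers source 100% or 50% of their rice intake from
biofortified varieties, another 5.3–10.6 million are reached through the
market, for a national coverage of 7–10%.

Results are tidy tibbles throughout:

```r
tidy(est)                      # one row per accounting ID, full precision
glance(est)                    # one-row summary with reach/coverage range
autoplot(est)                  # stacked on-farm/off-farm reach by scenario

ests <- lapply(reach_fixtures(), function(n) estimate_reach(reach_fixture(n)))
render_reach_table(ests)       # 31-row worksheet-style comparison table
#> 16 2H  Biofortified crop available for ... 2,640,819  9,980,420  1,095,556  3,196,561
#> 27 5A.1 Reach                              12,429,704 96,897,280 41,755,641 25,407,951
#> 30 5C.1 Coverage                           7          39         18         11

sensitivity_reach(reach_fixture("pakistan_zinc_wheat_2023"), "4B", 10)
#> off-farm population elasticity -0.909: a 10% higher national intake
#> spreads the same market quantity over ~9.1% fewer people

seed_ratio_method(est)         # full-mixing alternative, flagged if implausible
```

A thin CLI wraps the same functions:

```sh
exec/bioreach validate inst/extdata/fixtures/pakistan_zinc_wheat_2023.yaml
exec/bioreach run inst/extdata/fixtures/pakistan_zinc_wheat_2023.yaml --out results/
exec/bioreach sweep inst/extdata/fixtures/pakistan_zinc_wheat_2023.yaml --param 3C --range 5:8:7
```

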
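---
title: "Estimating the reach and coverage of biofortified crops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the reach and coverage of biofortified crops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioreach)
```

## The problem

Biofortified staple varieties (zinc rice and wheat, provitamin-A maize and
cassava, and others) are bred to carry more of a micronutrient than the
conventional crop. Program managers and policymakers need two performance
indicators: **reach**, the number of people consuming the biofortified food
in a year, and **coverage**, reach as a share of the national population.
Household surveys measure these poorly — many biofortified crops have no
visible trait, so respondents cannot tell whether the food they bought was
biofortified — and they are expensive to repeat annually.

`bioreach` implements an accounting alternative: follow the biofortified
crop from seed through production to consumption using a small set of
parameters from seed-producer censuses, farmer monitoring surveys, and
public databases (food balance sheets, area statistics, censuses,
population estimates). Everything is deterministic arithmetic on a
provenance-tagged parameter table, so estimates are cheap, reproducible,
and auditable.

## The five phases

Each parameter has an accounting ID (phase number + letter) used in
configs, results and tables.

**Phase 1 — seed availability.** Farmers plant commercial biofortified
seed plus farm-saved seed (FSS) kept from the previous harvest. Total seed
used is back-calculated from area and seed rate, and the FSS ratio from
its excess over commercial production:

$$
1D = 1B \times 1C, \qquad
1F = \max\!\left(0, \frac{1D - 1E}{1E}\right), \qquad
1G = 1A \times 1F, \qquad
1H = 1A + 1G
$$

where $1A$ is commercial biofortified seed, $1B$ total area harvested
(ha), $1C$ the seed rate, and $1E$ total commercial seed produced. Area
*harvested* proxies area *planted*; it is the conservative choice because
weather and pest losses shrink the harvested area, and no planting-loss
correction is applied. The FSS practice is assumed identical for
biofortified and conventional varieties.

Two defensible denominators exist for the FSS ratio (seed *used* or seed
*produced*); the published worked examples are numerically consistent only
with seed *produced* ($1E$), which is what the package implements.

**Phase 2 — production.** Seed becomes area, harvest, and edible supply:

$$
2B = \frac{1H}{2A}, \qquad 2D = 2B \times 2C, \qquad
2H = 2D \times (1 - 2E - 2F - 2G)
$$

with $2C$ the mean survey yield (MT/ha) and $2E$/$2F$/$2G$ the harvest
fractions retained as next-season seed, fed to animals, and lost
post-harvest (food-balance-sheet shares). When no survey yield exists for
the analysis year, `adjust_yield()` rescales the latest survey yield by
the ratio of national reference yields between the two years.

**Phase 3 — on-farm consumption.** Farming population and on-farm
tonnage:

$$
3D = 3B \times 3C, \qquad 3E = 3D \times 3A / 1000
$$

where $3B$ is the number of growing households, $3C$ the mean farming
household size, and $3A$ the annual per-capita on-farm intake (kg). Median
survey intakes are preferred over means because survey consumption
distributions are strongly right-skewed.

**Phase 4 — off-farm consumption.** The market receives the residual
$4A = 2H - 3E$. How many people that feeds depends on how much of a
market consumer's intake of the crop is biofortified, which no survey
measures; the package therefore evaluates *replacement scenarios*. Under
replacement fraction $r$, per-capita off-farm intake is $4B_r = r \times
4B$ (the national food-balance-sheet intake), and

$$
4C_r = \frac{4A \times 1000}{4B_r}.
$$

The defaults are the two standard scenarios, full replacement ($r = 1$)
and half replacement ($r = 0.5$); $r$ is a continuous parameter, so any
scenario list can be supplied. Off-farm population is exactly inversely
proportional to $r$.

**Phase 5 — reach and coverage.**

$$
5A_r = 3D + 4C_r, \qquad 5C_r = 100 \times \frac{5A_r}{5B}.
$$

A reach above the national population is reported with a plausibility
flag, never an exception: the arithmetic is the user's diagnostic.

## Units

Quantities carry units from a closed set. Mass seed (kg/MT) converts by
1000; cassava planting material is *counted* (bundles of stems, with a
bundles/ha rate) and never converts to mass — the chain only ever divides
bundles by bundles-per-hectare, so none is needed. Annual intakes convert
to g/day by 1000/365 for plausibility screening.

## Precision and rounding policy

All phases carry full double precision; rounding happens once, at report
time (`render_reach_table()`), half-up: counts, tonnages and percents to
integers; ratios, yields and household sizes to one decimal. Published
worked tables of this kind round intermediates inconsistently (a cell
computed from rounded precursors can differ by a few units in the last
digit from one computed at full precision), which is why internal rounding
is never applied: it compounds.

Config parameters accept an optional `value_precise` alongside the
published `value`. This exists because public sources often print rounded
figures (whole-percent food-balance shares, integer per-capita supplies)
while the accounting that produced companion figures used the unrounded
values; the shipped parameter sets use it for the feed shares and national
intakes. The golden-table tests compare chained cells within one unit of
the last printed digit or $10^{-5}$ relative, whichever is larger — the
package's reading of the inconsistent intermediate rounding in the
published worksheets.

## Degenerate inputs

- Commercial seed above the back-calculated requirement would make the
  FSS ratio negative: clamped to 0 with a warning and a `fss_clamped`
  flag.
- On-farm consumption above the edible supply would make the market
  quantity negative: clamped to 0 with a warning and an `offfarm_clamped`
  flag (mass balance $3E + 4A = 2H$ holds whenever no clamp fires).
- Deduction fractions must sum below 1; replacement fractions lie in
  (0, 1]; validation reports *every* violation with its parameter ID and
  never crashes on arbitrary input.

## The growing-household model

Parameter $3B$ can be supplied directly (the shipped parameter sets do) or
built from seed-distribution data. `households_from_packs()` counts one
acquiring household per seed pack sold where per-pack-size counts exist,
and divides bulk quantities by a typical purchase size otherwise.
`project_growers()` then carries the stock of growing households forward:

$$
H_t = H_{t-1}\,(1 + d)\,(1 - a) + A_t
$$

with diffusion rate $d$ (growers recruiting neighbours farmer-to-farmer)
and attrition rate $a$ (growers dropping the variety). The published
methodology names these three ingredients but not the recursion, so the
form above is this package's documented choice; applying diffusion before
attrition within a year (so the year's recruits are also exposed to
attrition) is the conservative ordering, and both rates are plain
arguments so survey-derived values can be substituted. With $d = a = 0$
the series is the cumulative sum of acquirers; with $a = 1$ it is each
year's acquirers alone. Whether publicly-distributed seed recipients
attrit at the same rate is a data question, not a model feature: split the
records by channel and project with different rates if needed.

## The seed-ratio alternative for off-farm intake

`seed_ratio_method()` evaluates a different off-farm assumption: complete
mixing of biofortified and conventional crop before market, so every
market consumer's biofortified intake is the biofortified share of seed
used ($s = 1H/1D$) times the national intake, and the off-farm population
is $4A \times 1000 / (s \times 4B)$. Because $s$ is small, this produces
much larger reach estimates than the replacement scenarios, and it ignores
that visible-trait crops are traded separately. Estimates are screened
against the national population and flagged when they exceed it. For the
shipped cassava parameter set this method computes a reach of about 224.7
million (98.6% of Nigeria's population): extreme but, from these printed
inputs, just *below* the population, so the flag does not fire — the
published account of the same exercise reports exceeding the population,
a difference that cannot be reconciled from the published figures alone
(the corresponding acceptance expectation is left failing rather than
adjusted). The wheat and maize cases reproduce the published alternative
figures to within 1%.

## Plausibility screening of intakes

`intake_plausibility()` converts annual intakes to g/person/day and flags
values outside 100–600 g/day by default. The band brackets plausible
staple consumption: national staple supplies run roughly 100–450
g/person/day, so a survey-derived 710 g/day (from 259 kg/year) flags
high — the situation in which a food-balance-sheet intake should be
substituted, as the Pakistan parameter set does. The bounds are arguments
because no standard threshold exists.

## What the synthetic generator does and does not emulate

`random_reach_config(seed)` draws schema-valid parameter sets whose ranges
bracket the four shipped country-crop sets by roughly an order of
magnitude each way, in both mass-seed and bundle-counted variants. The
on-farm side is drawn jointly with the computed edible supply so that
on-farm consumption stays inside it — the regime all four worked examples
occupy; the clamped regimes are exercised by dedicated unit tests instead.
The generator emulates the *arithmetic* envelope of real parameter sets,
not their empirical correlations (seed rates are not linked to crops, nor
yields to agro-ecology), so property tests built on it certify the
engine's algebra — mass balance, scenario scaling, monotonicity,
equivalence with a straight-line worksheet recomputation over 200 seeded
draws — not the realism of any particular configuration.

## Sensitivity analysis

`sensitivity_reach()` is deterministic one-at-a-time: perturb one
parameter by a given percentage, re-run, and report elasticities (percent
output change per percent input change) for the farming population,
off-farm population, reach and coverage per scenario. No Monte-Carlo
layer is provided because the parameter sources publish no distributions;
elasticities plus the provenance table are the honest uncertainty
statement available. Note the sign structure: household size moves the
farming population one-for-one, but its effect on *reach* depends on
whether the scenario's off-farm intake exceeds the on-farm intake (a tonne
moved from market to farm can feed fewer or more people).

## Problem sizes and limitations

All computations are closed-form arithmetic on ~13 inputs; the full test
suite, including the 200-configuration property sweep and all four
golden-table reproductions, runs in well under a minute.

Known limitations, inherited from the accounting design: imports and
exports of the biofortified crop are not modelled (config schema leaves
room for future terms); mixing along the value chain is represented only
by the two bracketing assumptions (replacement scenarios vs. complete
mixing); and every estimate is conditional on the parameter sources, which
is why each config value carries `source_type`, `citation` and year, and
why `bioreach run` echoes provenance with results.
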
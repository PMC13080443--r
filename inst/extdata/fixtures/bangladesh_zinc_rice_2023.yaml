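# Zinc biofortified rice, Bangladesh, 2023.
# `value` holds each parameter as published; `value_precise` carries the
# unrounded working value where the published figure is rounded (the
# food-balance feed share and the per-capita supply are published rounded,
# but the supply accounting they feed is only consistent with the unrounded
# FAOSTAT figures given here).
metadata:
  country: Bangladesh
  crop: rice
  nutrient: zinc
  year: 2023
scenarios:
  - {label: full replacement, replacement: 1.0}
  - {label: half replacement, replacement: 0.5}
parameters:
  "1A": {value: 7244, unit: MT, source_type: primary_survey,
         citation: "HarvestPlus census of biofortified seed producers", year: 2023}
  "1B": {value: 11641645, unit: ha, source_type: faostat,
         citation: "FAOSTAT Crops and livestock products, area harvested", year: 2023}
  "1C": {value: 30, unit: kg_per_ha, source_type: publication,
         citation: "Bangladesh Institute of Nuclear Agriculture (BINA) seed rate", year: 2023}
  "1E": {value: 146708, unit: MT, source_type: publication,
         citation: "Ministry of Agriculture, Bangladesh, total seed produced", year: 2023}
  "2C": {value: 5.6, unit: MT_per_ha, source_type: primary_survey,
         citation: "HarvestPlus farmer monitoring survey, mean yield", year: 2023}
  "2E": {value: 2, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, seed share", year: 2023}
  "2F": {value: 13, value_precise: 11.9626566264, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, feed share (unrounded)", year: 2023}
  "2G": {value: 4, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, losses share", year: 2023}
  "3A": {value: 187, unit: kg_per_person_year, source_type: primary_survey,
         citation: "HarvestPlus farmer monitoring survey, median on-farm intake", year: 2023}
  "3B": {value: 2552319, unit: households, source_type: primary_survey,
         citation: "HarvestPlus household growing model", year: 2023}
  "3C": {value: 2.8, unit: persons, source_type: census,
         citation: "Household Income and Expenditure Survey, rural mean household size", year: 2022}
  "4B": {value: 247, value_precise: 246.9, unit: kg_per_person_year, source_type: faostat,
         citation: "FAOSTAT Food balances, per-capita rice supply (unrounded)", year: 2023}
  "5B": {value: 171466990, unit: persons, source_type: worldbank,
         citation: "World Bank population estimate", year: 2023}
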
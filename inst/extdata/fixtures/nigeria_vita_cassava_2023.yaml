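# Vitamin A biofortified (yellow) cassava, Nigeria, 2023.
# Planting material is counted in bundles of stems (never converted to
# mass). No 2023 monitoring survey collected yields, so the published 2C is
# the 2022 survey yield rescaled by the FAOSTAT 2022->2023 national yield
# ratio: 8.2 * 6.3459 / 6.0145 = 8.65 MT/ha (see adjust_yield()); the
# value_precise carries that product unrounded.
metadata:
  country: Nigeria
  crop: cassava
  nutrient: vitamin A
  year: 2023
scenarios:
  - {label: full replacement, replacement: 1.0}
  - {label: half replacement, replacement: 0.5}
parameters:
  "1A": {value: 4845831, unit: bundles, source_type: primary_survey,
         citation: "HarvestPlus census of biofortified stem producers", year: 2023}
  "1B": {value: 9878773, unit: ha, source_type: faostat,
         citation: "FAOSTAT Crops and livestock products, area harvested", year: 2023}
  "1C": {value: 60, unit: bundles_per_ha, source_type: publication,
         citation: "IITA recommended cassava planting rate", year: 2023}
  "1E": {value: 79820000, unit: bundles, source_type: publication,
         citation: "National Agricultural Seeds Council stem production estimate", year: 2023}
  "2C": {value: 8.7, value_precise: 8.65182143154, unit: MT_per_ha, source_type: primary_survey,
         citation: "HarvestPlus 2022 farmer monitoring survey yield, rescaled by the FAOSTAT 2022->2023 yield ratio", year: 2022}
  "2E": {value: 0, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, seed share (stems are not part of the root harvest)", year: 2023}
  "2F": {value: 30, value_precise: 30.3949972258, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, feed share (unrounded)", year: 2023}
  "2G": {value: 8, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, losses share", year: 2023}
  "3A": {value: 89, unit: kg_per_person_year, source_type: primary_survey,
         citation: "HarvestPlus farmer monitoring survey, median on-farm intake", year: 2023}
  "3B": {value: 2236726, unit: households, source_type: primary_survey,
         citation: "HarvestPlus household growing model", year: 2023}
  "3C": {value: 5.6, unit: persons, source_type: primary_survey,
         citation: "HarvestPlus farmer monitoring survey, mean household size", year: 2018}
  "4B": {value: 162, value_precise: 161.6, unit: kg_per_person_year, source_type: faostat,
         citation: "FAOSTAT Food balances, per-capita cassava supply (unrounded)", year: 2023}
  "5B": {value: 227882945, unit: persons, source_type: worldbank,
         citation: "World Bank population estimate", year: 2023}
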
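# Vitamin A biofortified (orange) maize, Nigeria, 2023.
metadata:
  country: Nigeria
  crop: maize
  nutrient: vitamin A
  year: 2023
scenarios:
  - {label: full replacement, replacement: 1.0}
  - {label: half replacement, replacement: 0.5}
parameters:
  "1A": {value: 13282, unit: MT, source_type: primary_survey,
         citation: "HarvestPlus census of biofortified seed producers", year: 2023}
  "1B": {value: 5700000, unit: ha, source_type: faostat,
         citation: "FAOSTAT Crops and livestock products, area harvested", year: 2023}
  "1C": {value: 20, unit: kg_per_ha, source_type: publication,
         citation: "IITA recommended maize seed rate", year: 2023}
  "1E": {value: 60000, unit: MT, source_type: publication,
         citation: "Published national maize seed production estimate", year: 2023}
  "2C": {value: 1.5, unit: MT_per_ha, source_type: primary_survey,
         citation: "HarvestPlus farmer monitoring survey, mean yield", year: 2023}
  "2E": {value: 1, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, seed share", year: 2023}
  "2F": {value: 36, value_precise: 36.1163056716, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, feed share (unrounded)", year: 2023}
  "2G": {value: 5, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, losses share", year: 2023}
  "3A": {value: 20, unit: kg_per_person_year, source_type: primary_survey,
         citation: "HarvestPlus farmer monitoring survey, median on-farm intake", year: 2023}
  "3B": {value: 1962832, unit: households, source_type: primary_survey,
         citation: "HarvestPlus household growing model", year: 2023}
  "3C": {value: 9.1, unit: persons, source_type: primary_survey,
         citation: "HarvestPlus farmer monitoring survey, mean household size", year: 2023}
  "4B": {value: 31, value_precise: 30.9, unit: kg_per_person_year, source_type: faostat,
         citation: "FAOSTAT Food balances, per-capita maize supply (unrounded)", year: 2023}
  "5B": {value: 227882945, unit: persons, source_type: worldbank,
         citation: "World Bank population estimate", year: 2023}
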
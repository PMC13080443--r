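# Zinc biofortified wheat, Pakistan, 2023.
# The farmer-monitoring intake and household size failed plausibility
# screens, so the on-farm intake is the FAOSTAT per-capita supply and the
# household size the 2023 census rural mean (provenance below).
metadata:
  country: Pakistan
  crop: wheat
  nutrient: zinc
  year: 2023
scenarios:
  - {label: full replacement, replacement: 1.0}
  - {label: half replacement, replacement: 0.5}
parameters:
  "1A": {value: 179486, unit: MT, source_type: primary_survey,
         citation: "HarvestPlus census of biofortified seed producers", year: 2023}
  "1B": {value: 9032688, unit: ha, source_type: faostat,
         citation: "FAOSTAT Crops and livestock products, area harvested", year: 2023}
  "1C": {value: 120, unit: kg_per_ha, source_type: publication,
         citation: "Agribusiness Pakistan recommended wheat seed rate", year: 2023}
  "1E": {value: 511379, unit: MT, source_type: publication,
         citation: "Pakistan Economic Survey, total seed produced", year: 2023}
  "2C": {value: 3.5, unit: MT_per_ha, source_type: primary_survey,
         citation: "HarvestPlus farmer monitoring survey, mean yield", year: 2023}
  "2E": {value: 4, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, seed share", year: 2023}
  "2F": {value: 2, value_precise: 2.05519837, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, feed share (unrounded)", year: 2023}
  "2G": {value: 4, unit: percent, source_type: faostat,
         citation: "FAOSTAT Food balances, losses share", year: 2023}
  "3A": {value: 103, unit: kg_per_person_year, source_type: faostat,
         citation: "FAOSTAT Food balances, per-capita wheat supply (survey value implausible)", year: 2023}
  "3B": {value: 3276066, unit: households, source_type: primary_survey,
         citation: "HarvestPlus household growing model", year: 2023}
  "3C": {value: 6.3, unit: persons, source_type: census,
         citation: "2023 Census of Pakistan, rural mean household size", year: 2023}
  "4B": {value: 103, unit: kg_per_person_year, source_type: faostat,
         citation: "FAOSTAT Food balances, per-capita wheat supply", year: 2023}
  "5B": {value: 247504495, unit: persons, source_type: worldbank,
         citation: "World Bank population estimate", year: 2023}
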
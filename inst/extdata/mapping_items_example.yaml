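# Example column mapping for an item-level diet questionnaire.
# Each food group lists the source item columns it aggregates (OR rule).
cluster: cluster
stratum: stratum
weight: wt
age: age_m
age_unit: months
breastmilk: bm
groups:
  grains: [cereal]
  legumes: [beans]
  dairy: [milk, yogurt]
  flesh: [meat, fish]
  eggs: [egg]
  vita_fruit_veg: [pumpkin]
  other_fruit_veg: [mango]
truthy: ["1", "yes"]
na_codes: ["", "NA", ".", "9"]
household_id: hh_id
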
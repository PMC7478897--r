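# Documentation-only example: typical child-recode style variable names
# for a 24-hour diet recall module, exported to delimited text by the
# analyst beforehand (this package reads delimited text, not proprietary
# survey binaries).  Adjust item lists to the questionnaire actually used.
cluster: v001        # cluster / primary sampling unit
stratum: v023        # design stratum
weight: v005         # sampling weight (any positive scale)
age: child_age_months
age_unit: months
breastmilk: v409     # gave breastmilk in previous 24 h
groups:
  grains: [v414e, v414f]          # bread/grains; tubers/roots
  legumes: [v414o]                # beans, peas, lentils, nuts
  dairy: [v411, v411a, v414p]     # milk, infant formula, cheese/yogurt
  flesh: [v414h, v414m, v414n]    # meat; organ meat; fish
  eggs: [v414g]
  vita_fruit_veg: [v414i, v414j]  # pumpkin/carrots; dark leafy greens
  other_fruit_veg: [v414k, v414l] # mangoes/papayas; other fruit/veg
truthy: ["1", "yes"]
na_codes: ["", "NA", ".", "9"]
household_id: hhid
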
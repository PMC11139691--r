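- name: vegetables
  shape: adequacy
  field: vegetables
  x_zero: 0.0
  x_full: 200.0
  max_points: 10.0
- name: fruit
  shape: adequacy
  field: fruit
  x_zero: 0.0
  x_full: 200.0
  max_points: 10.0
- name: grains
  shape: ratio
  field: grains
  numerator: whole_grains
  denominator: refined_grains
  max_points: 10.0
- name: legumes
  shape: adequacy
  field: legumes
  x_zero: 0.0
  x_full: 10.0
  max_points: 10.0
- name: nuts
  shape: adequacy
  field: nuts_unsalted
  x_zero: 0.0
  x_full: 15.0
  max_points: 10.0
- name: dairy
  shape: optimum_range
  field: dairy
  x_zero: 0.0
  x_full: 300.0
  x_full_upper: 450.0
  x_zero_upper: 750.0
  max_points: 10.0
- name: fish
  shape: adequacy
  field: fish
  x_zero: 0.0
  x_full: 21.0
  max_points: 10.0
- name: tea
  shape: adequacy
  field: tea
  x_zero: 0.0
  x_full: 450.0
  max_points: 10.0
- name: fats_oils
  shape: ratio
  field: fats_oils
  numerator: liquid_fats
  denominator: solid_fats
  max_points: 10.0
- name: red_meat
  shape: moderation
  field: red_meat
  x_zero: 100.0
  x_full: 45.0
  max_points: 10.0
- name: processed_meat
  shape: moderation
  field: processed_meat
  x_zero: 50.0
  x_full: 0.0
  max_points: 10.0
- name: ssb_juice
  shape: moderation
  field: ssb_juice
  x_zero: 250.0
  x_full: 0.0
  max_points: 10.0
- name: alcohol
  shape: moderation
  field: alcohol
  x_zero: 30.0
  x_full: 10.0
  sex_specific:
    female:
      x_zero: 20.0
  max_points: 10.0
- name: sodium
  shape: moderation
  field: sodium
  x_zero: 3800.0
  x_full: 1900.0
  max_points: 10.0
- name: sterols
  shape: binary
  field: sterol_use
  max_points: 10.0
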
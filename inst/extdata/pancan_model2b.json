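{
  "name": "PanCan full model with spiculation (model 2b)",
  "provenance": "Coefficients as published by McWilliams et al., N Engl J Med 2013;369:910-919 (Brock University / Pan-Canadian Early Detection of Lung Cancer Study), full model including spiculation. Log-odds scale. Nodule size enters as -5.3854 * ((d_mm/10)^-0.5 - 1.58113883), i.e. centred at a 4 mm nodule; age is centred at 62 years and the per-scan nodule count (total nodules on the scan) at 4.",
  "intercept": -6.8272,
  "beta_age": 0.0287,
  "age_center": 62,
  "beta_sex_female": 0.6011,
  "beta_family_history": 0.2961,
  "beta_emphysema": 0.2953,
  "beta_size": -5.3854,
  "size_transform": {
    "type": "power",
    "scale_mm": 10,
    "power": -0.5,
    "offset": 1.58113883
  },
  "beta_nonsolid": -0.1276,
  "beta_partsolid": 0.377,
  "beta_upper_lobe": 0.6581,
  "beta_count": -0.0824,
  "count_center": 4,
  "count_variable": "total",
  "beta_spiculation": 0.7729
}
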
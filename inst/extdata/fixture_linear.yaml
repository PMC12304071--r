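# Synthetic physiology parameter set with linear bodyweight dependence.
# Identical to the built-in "fixture_linear" set; kept as a worked example of
# the physiology-config dialect (see ?physiology_set_from_config).
# Canonical units: gfr/qr L/h, kidney_weight g, concentrations g/L.
name: fixture_linear_yaml
reference: synthetic linear fixture (not from literature)
parameters:
  gfr:           {intercept: 6.5,  slope: 0.04,  ref_bodyweight: 59.2}
  qr:            {intercept: 60,   slope: 0.25,  ref_bodyweight: 59.2}
  kidney_weight: {intercept: 300,  slope: 1.5,   ref_bodyweight: 59.2}
  hsa_conc:      {intercept: 45,   slope: -0.03, ref_bodyweight: 59.2}
  aag_conc:      {intercept: 0.8,  slope: 0.004, ref_bodyweight: 59.2}
  hematocrit:    {male: 0.45, female: 0.40}
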
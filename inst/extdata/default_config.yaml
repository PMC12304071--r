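# Default study configuration: six BMI categories at 1.72 m, the full
# factorial drug grid, both binding proteins, flat dosing and AS0.75.
physiology_set: fixture_linear
height: 1.72
sex: male
bmi_categories: [20, 25, 30, 40, 50, 60]
baseline_bmi: 20
grid:
  fu_normal_weight: [0.05, 0.25, 0.50, 0.75, 0.95, 1.00]
  kp: [0.35, 1, 2, 3, 4, 5, 10, 20, 30, 40]
  clint_ats: {from: 2, to: 500, length: 32}   # ul/min per mg protein
  rta: [0.2, 0.5, 1.0, 1.5, 2.0, 2.5]
  binding_protein: [HSA, AAG]
exponents: [0, 0.75]
pe_threshold: 30
ptcpgk: 99.4
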
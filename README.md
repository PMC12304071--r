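# renalscale

Renal drug clearance changes with obesity, but not uniformly: glomerular
filtration rate, renal blood flow, kidney mass and the plasma concentrations
of the two major drug-binding proteins (human serum albumin, HSA, which falls
with BMI, and alpha-1 acid glycoprotein, AAG, which rises) all shift in
different directions and to different degrees. Whether the renal clearance
(CLr) of a given drug rises, stalls or is effectively flat across BMI 20–60
kg/m² therefore depends on the drug's unbound fraction, its binding protein,
its blood-cell partitioning and how strongly it is secreted by proximal
tubule transporters — and on whether obesity alters transporter activity at
all, which is largely unknown.

`renalscale` is a simulation toolkit for exactly this question. It is aimed
at clinical pharmacologists and PK modellers who need to judge, *a priori*,
whether simple bodyweight-based clearance scaling (flat dosing, or allometric
scaling with exponent 0.75) is safe for a renally cleared drug in overweight
and obese patients, or whether a mechanistic (PBPK) prediction is required.

## The model

Total renal clearance is the sum of glomerular filtration and active tubular
secretion (reabsorption and renal metabolism are deliberately out of scope):

```
CLr    = CL_GF + CL_ATS
CL_GF  = fu × GFR
CL_ATS = ((Qr − GFR) × fu × CLint_sec) / (Qr + fu × CLint_sec / BP)
```

with `fu` the unbound plasma fraction (rescaled to each subject's
binding-protein concentration under constant binding affinity),
`BP = 1 + Hct (fu·Kp − 1)` the blood-to-plasma ratio, and
`CLint_sec = CLint_ATS × kidney weight × PTCPGK × rTA` the whole-kidney
intrinsic secretion clearance (rTA = relative transporter activity, 1 =
unchanged from normal weight).

Hypothetical drugs are enumerated on a full factorial grid — 6 unbound
fractions × 10 Kp values × 32 equidistant intrinsic secretion clearances
(2–500 µl·min⁻¹·mg⁻¹) × 6 rTA scenarios = 11,520 combinations, run in
parallel for HSA- and AAG-bound drugs — and evaluated in six typical virtual
subjects (BMI 20, 25, 30, 40, 50, 60 kg/m² at height 1.72 m). For every
drug × scenario, allometric scaling from the normal-weight subject,

```
scaled CLr = CLr_normal × (BW/BW_normal)^exponent
PE (%)     = 100 × (scaled CLr − PBPK CLr) / PBPK CLr
```

is judged against the PBPK value; a stratum is *systematically accurate* when
every drug in it has |PE| ≤ 30%. The exponent that would scale exactly,
`ln(CLr/CLr_normal) / ln(BW/BW_normal)`, is reported per row.

Subject physiology comes from pluggable parameter sets mapping BMI (and sex)
to GFR, renal blood flow, kidney weight, HSA/AAG concentrations and
hematocrit. The package ships a synthetic `fixture_linear` set with the
expected qualitative obesity trends; the name `berton2022` is reserved for
the published BMI-dependent equations of Berton and colleagues, whose
coefficients are not redistributed here — transcribe them into a small YAML
file and load them with `physiology_set_from_config()` (see
`inst/extdata/fixture_linear.yaml` for the dialect).

## Worked example

```r
library(renalscale)

make_subjects(c(20, 30, 40))
#>     bmi height sex   bodyweight   gfr    qr kidney_weight hsa_conc aag_conc hematocrit ptcpgk
#> 1    20   1.72 male        59.2  6.50  60.0          300.     45.0    0.800       0.45   99.4
#> 2    30   1.72 male        88.8  7.68  67.4          344.     44.1    0.918       0.45   99.4
#> 3    40   1.72 male       118.   8.87  74.8          389.     43.2    1.04        0.45   99.4

cfg   <- run_config(grid = list(kp = 1, clint_ats = c(2, 100, 500)))
study <- run_study(cfg)
study
#> <clr_study>
#>   subjects: 6 | drugs: 36 | clearance rows: 1296 | scaling rows: 2160
#>   exponent 0.00: 9 / 60 strata systematically accurate
#>   exponent 0.75: 10 / 60 strata systematically accurate

dplyr::filter(tidy(study, "verdicts"), rta == 1, bmi %in% c(25, 30))
#>     bmi   rta binding_protein exponent n_drugs max_abs_pe systematically_accurate
#> 1    25     1 AAG                 0         18       7.77 TRUE
#> 2    25     1 AAG                 0.75      18      16.9  TRUE
#> 3    25     1 HSA                 0         18       8.63 TRUE
#> 4    25     1 HSA                 0.75      18      11.3  TRUE
#> 5    30     1 AAG                 0         18      14.4  TRUE
#> 6    30     1 AAG                 0.75      18      32.6  FALSE
#> 7    30     1 HSA                 0         18      16.0  TRUE
#> 8    30     1 HSA                 0.75      18      20.5  TRUE
```

The subject table shows the fixture physiology: GFR, renal blood flow,
kidney weight and AAG rise with BMI while HSA falls. The study object holds
tidy tables (`tidy(study, "clearance")`, `"scaling"`, `"verdicts"`,
`"exponent_ranges"`); the verdict rows above say that with unchanged
transporter activity (rTA = 1) every drug in this reduced grid is scaled
within ±30% at BMI 25 under both exponents, while at BMI 30 one stratum
(AAG, exponent 0.75, worst |PE| 32.6%) already breaks systematic accuracy
under this synthetic physiology. `autoplot(study, "relative_clr")` and
`autoplot(study, "prediction_error")` draw the corresponding panels; a thin
command-line wrapper lives in `inst/cli/renalscale.R`.

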
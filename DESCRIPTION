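Package: renalscale
Title: PBPK Simulation of Renal Drug Clearance in Obesity and Evaluation
    of Allometric Clearance Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates renal drug clearance through glomerular filtration
    and active tubular secretion for factorial grids of hypothetical drugs
    in virtual subjects spanning body mass index 20 to 60 kg/m2, using a
    physiologically based pharmacokinetic (PBPK) clearance model.
    Physiological system parameters (glomerular filtration rate, renal
    blood flow, kidney weight, plasma binding-protein concentrations,
    hematocrit) are generated from BMI via pluggable parameter sets.
    Downstream tools evaluate the accuracy of allometric bodyweight
    scaling of clearance (flat dosing, exponent 0.75, or any exponent),
    compute signed prediction errors against the PBPK reference, classify
    systematic scaling accuracy per stratum, and derive the allometric
    exponent required for exact scaling. All results are tidy tibbles with
    ggplot2 visualisation helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
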
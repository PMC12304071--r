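test_that("bodyweight derivation reproduces the study's category weights", {
  # six BMI categories at the 1.72 m reference height
  expect_equal(bodyweight_from_bmi(c(20, 25, 30, 40, 60)),
               c(59.2, 74.0, 88.8, 118.3, 177.5))
  # raw arithmetic at BMI 50 gives 147.92
  expect_equal(bodyweight_from_bmi(50), 147.9, tolerance = 0.1)
  expect_equal(bodyweight_from_bmi(25, height = 2), 100)
  # unrounded value available for internal use
  expect_equal(bodyweight_from_bmi(20, digits = NULL), 20 * 1.72^2)
  expect_error(bodyweight_from_bmi(-1), "positive")
  expect_error(bodyweight_from_bmi(20, height = 0), "positive")
})

test_that("make_subjects populates all fields in canonical units and is deterministic", {
  subs <- make_subjects(c(20, 25, 30, 40, 50, 60))
  expect_s3_class(subs, "tbl_df")
  expect_equal(nrow(subs), 6)
  expect_named(subs, c("bmi", "height", "sex", "bodyweight", "gfr", "qr",
                       "kidney_weight", "hsa_conc", "aag_conc",
                       "hematocrit", "ptcpgk"))
  # bodyweight invariant bmi * height^2
  expect_equal(subs$bodyweight, subs$bmi * subs$height^2, tolerance = 1e-12)
  expect_true(all(subs$ptcpgk == 99.4))
  # fixture baseline values at BMI 20
  base <- subs[subs$bmi == 20, ]
  expect_equal(base$gfr, 6.5 + 0.04 * (base$bodyweight - 59.2))
  expect_equal(base$qr, 60 + 0.25 * (base$bodyweight - 59.2))
  expect_equal(base$hematocrit, 0.45)
  # physiological validity across the range
  expect_true(all(subs$qr > subs$gfr))
  expect_true(all(subs$hematocrit > 0 & subs$hematocrit < 1))
  expect_true(all(subs$gfr > 0 & subs$kidney_weight > 0 &
                    subs$hsa_conc > 0 & subs$aag_conc > 0))
  # determinism
  expect_identical(subs, make_subjects(c(20, 25, 30, 40, 50, 60)))
  # sex switch only affects hematocrit in the fixture set
  f <- make_subjects(20, sex = "female")
  expect_equal(f$hematocrit, 0.40)
  expect_equal(f$gfr, base$gfr)
})

test_that("make_subjects validates inputs and warns on extrapolation", {
  expect_warning(make_subjects(70), "outside")
  expect_warning(make_subjects(15), "outside")
  expect_error(make_subjects(-5), "positive")
  expect_error(make_subjects(20, height = -1), "positive")
  expect_error(make_subjects(20, params = "no_such_set"), "unknown")
  # a parameter function returning a non-positive value is caught and named
  bad <- new_physiology_set("bad", list(
    gfr = function(bmi, sex, bodyweight) -1,
    qr = function(bmi, sex, bodyweight) 60,
    kidney_weight = function(bmi, sex, bodyweight) 300,
    hsa_conc = function(bmi, sex, bodyweight) 45,
    aag_conc = function(bmi, sex, bodyweight) 0.8,
    hematocrit = function(bmi, sex, bodyweight) 0.45
  ))
  expect_error(make_subjects(20, params = bad), "gfr")
})

test_that("fixture physiology follows the expected obesity directions", {
  subs <- make_subjects(c(20, 25, 30, 40, 50, 60))
  mono_up <- function(x) all(diff(x) > 0)
  expect_true(mono_up(subs$gfr))
  expect_true(mono_up(subs$qr))
  expect_true(mono_up(subs$kidney_weight))
  expect_true(mono_up(subs$aag_conc))
  expect_true(all(diff(subs$hsa_conc) < 0))
  expect_true(all(subs$hematocrit == subs$hematocrit[1]))
})

test_that("relative_parameters returns unit ratios at baseline and correct ratios elsewhere", {
  subs <- make_subjects(c(20, 40))
  rel <- relative_parameters(subs)
  at_base <- rel[rel$bmi == 20, ]
  expect_true(all(at_base$ratio == 1))
  r_gfr <- rel$ratio[rel$bmi == 40 & rel$parameter == "gfr"]
  expect_equal(r_gfr, subs$gfr[2] / subs$gfr[1])
  expect_error(relative_parameters(subs, baseline_bmi = 30), "baseline")
})

test_that("the berton2022 name is reserved and errors until a transcription is registered", {
  expect_error(physiology_set("berton2022"), "transcribed")
})

test_that("physiology sets load from a YAML config and match the built-in fixture", {
  path <- system.file("extdata", "fixture_linear.yaml", package = "renalscale")
  set <- physiology_set_from_config(path, register = FALSE)
  a <- make_subjects(c(20, 40, 60), params = set)
  b <- make_subjects(c(20, 40, 60), params = "fixture_linear")
  expect_equal(a[, -(1:3)], b[, -(1:3)], tolerance = 1e-12)
})
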
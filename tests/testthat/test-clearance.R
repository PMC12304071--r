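test_that("rescale_fu follows the constant-affinity binding relation", {
  # unchanged protein concentration leaves fu unchanged
  expect_equal(rescale_fu(0.05, 1), 0.05)
  expect_equal(rescale_fu(c(0.25, 0.75), 1), c(0.25, 0.75))
  # a fully unbound drug is insensitive to protein concentration
  expect_equal(rescale_fu(1, 2), 1)
  expect_equal(rescale_fu(1, 0.1), 1)
  # direct evaluation: fu_nw / (fu_nw + (1 - fu_nw) * ratio)
  expect_equal(rescale_fu(0.05, 0.8), 0.05 / (0.05 + 0.95 * 0.8))
  # strictly decreasing in the protein ratio
  ratios <- seq(0.5, 2, by = 0.1)
  expect_true(all(diff(rescale_fu(0.3, ratios)) < 0))
  expect_error(rescale_fu(0.05, 0), "positive")
  expect_error(rescale_fu(0, 1), "\\(0, 1\\]")
})

test_that("blood_to_plasma is the hematocrit-weighted partition identity", {
  expect_equal(blood_to_plasma(0.45, 1, 1), 1)     # fu*Kp = 1
  expect_equal(blood_to_plasma(0, 0.5, 10), 1)     # no red cells
  expect_equal(blood_to_plasma(0.45, 1, 0.35), 1 + 0.45 * (0.35 - 1))
  # lower bound 1 - hematocrit
  fu <- runif(50); kp <- runif(50, 0.05, 40); h <- runif(50, 0.2, 0.55)
  expect_true(all(blood_to_plasma(h, fu, kp) >= 1 - h - 1e-12))
  expect_error(blood_to_plasma(1, 0.5, 1), "hematocrit")
})

test_that("total intrinsic secretion clearance is the unit-converted product", {
  # 2 * 99.4 * 300 ul/min = 59,640 ul/min = 3.5784 L/h
  expect_equal(total_clint_sec(2, 300, 99.4, 1), 3.5784)
  expect_equal(total_clint_sec(5, 300, 99.4, 0), 0)
  # linear in clint_ats and rta
  expect_equal(total_clint_sec(500, 300, 99.4, 2.5),
               2.5 * 250 * total_clint_sec(2, 300, 99.4, 1))
  expect_error(total_clint_sec(-1, 300), "non-negative")
})

test_that("glomerular filtration clearance is fu * GFR", {
  expect_equal(cl_gf(1, 7.2), 7.2)
  expect_equal(cl_gf(0, 7.2), 0)
  expect_equal(cl_gf(0.5, 6.5), 3.25)
  expect_error(cl_gf(1.2, 7), "\\[0, 1\\]")
})

test_that("secretion clearance matches direct evaluation and its analytic limits", {
  expect_equal(cl_ats(60, 6, 0.5, 0, 1), 0)
  expect_equal(cl_ats(60, 6, 0.5, 20, 1), 540 / 70)
  # flow-limited upper bound (qr - gfr) * bp as clint_sec -> Inf
  expect_equal(cl_ats(60, 6, 0.5, 1e9, 2), 108, tolerance = 1e-6)
  # low-clint linearisation (qr - gfr) * fu * clint_sec / qr
  expect_equal(cl_ats(60, 6, 0.5, 1e-6, 1.4),
               54 * 0.5 * 1e-6 / 60, tolerance = 1e-6)
  expect_error(cl_ats(6, 6, 0.5, 1, 1), "exceed")
})

test_that("secretion clearance agrees with an independent extraction-ratio oracle", {
  # oracle: unbound-availability form. With u = fu*CLint/(BP*Qr), the
  # post-glomerular extraction gives CL = (Qr - GFR) * BP * u / (1 + u).
  oracle <- function(qr, gfr, fu, cls, bp) {
    u <- fu * cls / (bp * qr)
    (qr - gfr) * bp * u / (1 + u)
  }
  set.seed(42)
  n <- 100
  qr <- runif(n, 30, 120)
  gfr <- qr * runif(n, 0.05, 0.5)
  fu <- runif(n, 0.01, 1)
  cls <- 10^runif(n, -2, 4)
  bp <- runif(n, 0.5, 20)
  got <- cl_ats(qr, gfr, fu, cls, bp)
  want <- oracle(qr, gfr, fu, cls, bp)
  expect_equal(got, want, tolerance = 1e-12)
  # strict flow-limit bound for all finite clint_sec
  expect_true(all(got < (qr - gfr) * bp))
})

test_that("secretion clearance is monotone in intrinsic clearance, fu and rTA", {
  cls <- seq(0.1, 2000, length.out = 60)
  expect_true(all(diff(cl_ats(60, 6, 0.4, cls, 1.2)) > 0))
  fu <- seq(0.01, 1, length.out = 40)
  expect_true(all(diff(cl_ats(60, 6, fu, 50, 1.2)) > 0))
  # rTA enters linearly through clint_sec
  rta <- c(0.2, 0.5, 1, 1.5, 2, 2.5)
  v <- cl_ats(60, 6, 0.4, total_clint_sec(100, 300, 99.4, rta), 1.2)
  expect_true(all(diff(v) > 0))
})

test_that("batch renal clearance composes the pieces and respects invariants", {
  subs <- make_subjects(c(20, 30, 60))
  drugs <- drug_grid(list(fu_normal_weight = c(0.05, 0.5, 1),
                          kp = c(0.35, 1, 5), clint_ats = c(2, 100, 500),
                          rta = 1, bmi = 1,
                          binding_protein = c("HSA", "AAG")))
  res <- renal_clearance(subs, drugs, rta = c(0.5, 1, 2))
  expect_equal(nrow(res), nrow(drugs) * 3 * 3)
  # additivity at machine precision
  expect_identical(res$clr, res$cl_gf + res$cl_ats)
  # contributions sum to 100
  expect_equal(res$contribution_gf + res$contribution_ats,
               rep(100, nrow(res)), tolerance = 1e-9)
  # relative CLr is exactly 100% at the baseline scenario
  at_base <- res[res$bmi == 20 & res$rta == 1, ]
  expect_equal(at_base$relative_clr, rep(100, nrow(at_base)))
  # fu bounds
  expect_true(all(res$fu > 0 & res$fu <= 1))
  # fully unbound drugs are protein-label invariant
  unb <- res[res$fu_normal_weight == 1, ]
  hsa <- unb[unb$binding_protein == "HSA",
             setdiff(names(unb), "binding_protein")]
  aag <- unb[unb$binding_protein == "AAG",
             setdiff(names(unb), "binding_protein")]
  expect_equal(as.data.frame(hsa), as.data.frame(aag), tolerance = 1e-12)
})

test_that("switching secretion off leaves pure filtration", {
  subs <- make_subjects(c(20, 40))
  drugs <- drug_grid(list(fu_normal_weight = 0.5, kp = 1, clint_ats = 2,
                          rta = 1, bmi = 1, binding_protein = "HSA"))
  drugs$clint_ats <- 0
  res <- renal_clearance(subs, drugs, rta = 1)
  expect_equal(res$clr, res$cl_gf)
  expect_equal(res$contribution_gf, rep(100, nrow(res)))
})

test_that("binding-protein direction drives relative clearance in the fixture set", {
  # HSA falls with BMI -> fu rises -> CL_GF rises faster than GFR alone;
  # AAG rises with BMI -> fu falls -> CL_GF dampened for highly bound drugs.
  subs <- make_subjects(c(20, 60))
  drugs <- drug_grid(list(fu_normal_weight = 0.05, kp = 1, clint_ats = 2,
                          rta = 1, bmi = 1,
                          binding_protein = c("HSA", "AAG")))
  res <- renal_clearance(subs, drugs, rta = 1)
  gf <- function(prot, bmi) res$cl_gf[res$binding_protein == prot &
                                        res$bmi == bmi]
  expect_gt(gf("HSA", 60), gf("HSA", 20))
  gfr_ratio <- subs$gfr[2] / subs$gfr[1]
  expect_gt(gf("HSA", 60) / gf("HSA", 20), gfr_ratio)
  expect_lt(gf("AAG", 60) / gf("AAG", 20), gfr_ratio)
})

test_that("relative_clr helper is plain percentage arithmetic", {
  expect_equal(relative_clr(5, 5), 100)
  expect_equal(relative_clr(6.5, 5), 130)
  expect_equal(relative_clr(3.5, 5), 70)
  expect_error(relative_clr(1, 0), "positive")
})
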
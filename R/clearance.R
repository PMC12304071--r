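# PBPK renal clearance model: total renal clearance is the sum of glomerular
# filtration (CL_GF = fu * GFR) and active tubular secretion (CL_ATS, a
# flow-limited well-stirred expression in the post-glomerular renal blood
# flow Qr - GFR). Tubular reabsorption and renal metabolism are deliberately
# out of scope.

#' Rescale the unbound plasma fraction to a new binding-protein concentration
#'
#' Drug-protein affinity is assumed constant across BMI, so under linear
#' (non-saturable) binding the unbound fraction depends only on the binding
#' protein's plasma concentration:
#' `fu = fu_nw / (fu_nw + (1 - fu_nw) * protein_ratio)`,
#' where `protein_ratio` is the subject's binding-protein concentration
#' relative to the normal-weight subject. The result decreases as the protein
#' concentration rises, equals `fu_nw` at ratio 1, and stays 1 for a fully
#' unbound drug.
#'
#' @param fu_normal_weight Unbound fraction in the normal-weight subject,
#'   in (0, 1].
#' @param protein_ratio Binding-protein concentration ratio
#'   (subject / normal weight), > 0.
#' @return Unbound fraction in the subject at hand.
#' @examples
#' rescale_fu(0.05, 0.8)
#' @export
rescale_fu <- function(fu_normal_weight, protein_ratio) {
  if (any(fu_normal_weight <= 0) || any(fu_normal_weight > 1)) {
    abort("`fu_normal_weight` must lie in (0, 1].")
  }
  if (any(protein_ratio <= 0)) abort("`protein_ratio` must be positive.")
  fu_normal_weight /
    (fu_normal_weight + (1 - fu_normal_weight) * protein_ratio)
}

#' Blood-to-plasma concentration ratio
#'
#' Hematocrit-weighted partition identity
#' `BP = 1 + Hct * (fu * Kp - 1)`: whole blood is the volume-weighted mix of
#' plasma and blood cells, with the cell/plasma concentration ratio given by
#' the unbound fraction times the blood-cell partition coefficient.
#'
#' @param hematocrit Volume fraction of red cells, in (0, 1) (0 allowed and
#'   returns 1).
#' @param fu Unbound plasma fraction, in \[0, 1\].
#' @param kp Blood-cell partition coefficient, > 0.
#' @return Blood-to-plasma ratio (always at least `1 - hematocrit`).
#' @examples
#' blood_to_plasma(0.45, 1, 0.35)
#' @export
blood_to_plasma <- function(hematocrit, fu, kp) {
  if (any(hematocrit < 0) || any(hematocrit >= 1)) {
    abort("`hematocrit` must lie in [0, 1).")
  }
  if (any(fu < 0) || any(fu > 1)) abort("`fu` must lie in [0, 1].")
  if (any(kp <= 0)) abort("`kp` must be positive.")
  1 + hematocrit * (fu * kp - 1)
}

#' Whole-kidney intrinsic secretion clearance
#'
#' Scales the per-mg-protein intrinsic transporter clearance to the whole
#' kidney: the product of `clint_ats` (ul/min per mg protein), kidney weight
#' (g), the proximal tubule cellularity scalar PTCPGK (per g kidney) and the
#' relative transporter activity, converted from ul/min to L/h
#' (factor 60 / 1e6).
#'
#' @param clint_ats Intrinsic active-secretion clearance, ul/min per mg
#'   protein, >= 0.
#' @param kidney_weight Total kidney mass, g.
#' @param ptcpgk Proximal tubule cells per gram kidney (study value 99.4).
#' @param rta Relative transporter activity, fraction of normal-weight
#'   activity (1 = unchanged), >= 0.
#' @return Total intrinsic secretion clearance CL_int_sec, L/h.
#' @examples
#' total_clint_sec(2, 300, 99.4, 1) # 3.5784 L/h
#' @export
total_clint_sec <- function(clint_ats, kidney_weight, ptcpgk = 99.4, rta = 1) {
  if (any(clint_ats < 0) || any(kidney_weight < 0) || any(ptcpgk < 0) ||
      any(rta < 0)) {
    abort("all inputs to `total_clint_sec()` must be non-negative.")
  }
  clint_ats * kidney_weight * ptcpgk * rta * 60 / 1e6
}

#' Glomerular filtration clearance
#'
#' `CL_GF = fu * GFR`: only unbound drug is filtered.
#'
#' @param fu Unbound plasma fraction, in \[0, 1\].
#' @param gfr Glomerular filtration rate, L/h.
#' @return Filtration clearance, L/h.
#' @export
cl_gf <- function(fu, gfr) {
  if (any(fu < 0) || any(fu > 1)) abort("`fu` must lie in [0, 1].")
  if (any(gfr <= 0)) abort("`gfr` must be positive.")
  fu * gfr
}

#' Active tubular secretion clearance
#'
#' Flow-limited secretion from post-glomerular renal blood:
#' `CL_ATS = ((Qr - GFR) * fu * CLint_sec) / (Qr + fu * CLint_sec / BP)`.
#' The value rises monotonically with intrinsic clearance and unbound
#' fraction, and saturates at the perfusion limit `(Qr - GFR) * BP` as
#' `CLint_sec` grows; for small `CLint_sec` it is approximately
#' `(Qr - GFR) * fu * CLint_sec / Qr`.
#'
#' @param qr Renal blood flow, L/h; must exceed `gfr`.
#' @param gfr Glomerular filtration rate, L/h.
#' @param fu Unbound plasma fraction, in \[0, 1\].
#' @param clint_sec Whole-kidney intrinsic secretion clearance, L/h
#'   (see [total_clint_sec()]).
#' @param bp Blood-to-plasma ratio (see [blood_to_plasma()]).
#' @return Secretion clearance, L/h.
#' @examples
#' cl_ats(60, 6, 0.5, 20, 1)
#' @export
cl_ats <- function(qr, gfr, fu, clint_sec, bp) {
  if (any(gfr <= 0)) abort("`gfr` must be positive.")
  if (any(qr <= gfr)) {
    abort("`qr` must exceed `gfr`: the secretion model needs positive post-glomerular flow.")
  }
  if (any(fu < 0) || any(fu > 1)) abort("`fu` must lie in [0, 1].")
  if (any(clint_sec < 0)) abort("`clint_sec` must be non-negative.")
  if (any(bp <= 0)) abort("`bp` must be positive.")
  ((qr - gfr) * fu * clint_sec) / (qr + fu * clint_sec / bp)
}

#' Relative renal clearance
#'
#' Renal clearance of a subject expressed as a percentage of the
#' normal-weight subject's clearance for the same drug.
#'
#' @param clr Subject's renal clearance, L/h.
#' @param clr_baseline Normal-weight clearance, L/h, > 0.
#' @return Percentage (100 = unchanged).
#' @export
relative_clr <- function(clr, clr_baseline) {
  if (any(clr_baseline <= 0)) abort("`clr_baseline` must be positive.")
  100 * clr / clr_baseline
}

#' Renal clearance for drugs crossed with subjects and transporter scenarios
#'
#' Evaluates the full clearance model for every drug x subject x rTA
#' combination: the unbound fraction is rescaled with the subject's
#' binding-protein concentration (HSA or AAG) relative to the normal-weight
#' baseline subject, the blood-to-plasma ratio and whole-kidney intrinsic
#' secretion clearance are formed, and CL_GF, CL_ATS and total CLr are
#' computed with their percentage pathway contributions. Relative CLr
#' compares each row against the same drug in the baseline subject with
#' unchanged transporter activity (rTA = 1).
#'
#' @param subjects Subject table from [make_subjects()]; must contain the
#'   baseline BMI row.
#' @param drugs Drug table from [drug_grid()] (columns `fu_normal_weight`,
#'   `kp`, `clint_ats`, `binding_protein`).
#' @param rta Numeric vector of relative transporter activities to cross in.
#' @param baseline_bmi BMI of the normal-weight reference subject,
#'   default 20.
#'
#' @return A tibble with the drug and scenario columns plus `fu`, `bp`,
#'   `clint_sec`, `cl_gf`, `cl_ats`, `clr` (all clearances in L/h),
#'   `contribution_gf`, `contribution_ats` and `relative_clr` (percent).
#'   Contributions are `NA` when `clr` is 0.
#' @examples
#' subs <- make_subjects(c(20, 40))
#' drugs <- drug_grid()[c(1, 500), ]
#' renal_clearance(subs, drugs, rta = 1)
#' @export
renal_clearance <- function(subjects, drugs, rta = default_grid_values()$rta,
                            baseline_bmi = 20) {
  if (!baseline_bmi %in% subjects$bmi) {
    abort(paste0("`subjects` must include the baseline BMI (",
                 baseline_bmi, ")."))
  }
  if (any(rta <= 0)) abort("`rta` values must be positive.")
  base_sub <- subjects[subjects$bmi == baseline_bmi, , drop = FALSE][1, ]

  rows <- drugs %>%
    cross_join(tibble(bmi = subjects$bmi)) %>%
    cross_join(tibble(rta = as.numeric(rta))) %>%
    left_join(subjects, by = "bmi")

  out <- .evaluate_clearance(rows, base_sub)

  # same-drug baseline (BMI = baseline, rTA = 1) for relative CLr
  base_rows <- drugs %>%
    mutate(bmi = baseline_bmi, rta = 1) %>%
    left_join(subjects, by = "bmi")
  base_clr <- .evaluate_clearance(base_rows, base_sub) %>%
    select("fu_normal_weight", "kp", "clint_ats", "binding_protein",
           clr_baseline = "clr")

  out %>%
    left_join(base_clr,
              by = c("fu_normal_weight", "kp", "clint_ats",
                     "binding_protein")) %>%
    mutate(relative_clr = if_else(.data$clr_baseline > 0,
                                  100 * .data$clr / .data$clr_baseline,
                                  NA_real_)) %>%
    select(-"clr_baseline")
}

# rows: one row per drug x subject x rta, with subject columns joined in.
.evaluate_clearance <- function(rows, base_sub) {
  rows %>%
    mutate(
      protein_ratio = if_else(.data$binding_protein == "HSA",
                              .data$hsa_conc / base_sub$hsa_conc,
                              .data$aag_conc / base_sub$aag_conc),
      fu = rescale_fu(.data$fu_normal_weight, .data$protein_ratio),
      bp = blood_to_plasma(.data$hematocrit, .data$fu, .data$kp),
      clint_sec = total_clint_sec(.data$clint_ats, .data$kidney_weight,
                                  .data$ptcpgk, .data$rta),
      cl_gf = cl_gf(.data$fu, .data$gfr),
      cl_ats = cl_ats(.data$qr, .data$gfr, .data$fu, .data$clint_sec,
                      .data$bp),
      clr = .data$cl_gf + .data$cl_ats,
      contribution_gf = if_else(.data$clr > 0,
                                100 * .data$cl_gf / .data$clr, NA_real_),
      contribution_ats = if_else(.data$clr > 0,
                                 100 * .data$cl_ats / .data$clr, NA_real_)
    ) %>%
    select("fu_normal_weight", "kp", "clint_ats", "binding_protein",
           "bmi", "rta", "bodyweight", "fu", "bp", "clint_sec",
           "cl_gf", "cl_ats", "clr", "contribution_gf", "contribution_ats")
}
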
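# Allometric clearance scaling and its evaluation against the PBPK-predicted
# "true" clearance. Exponent 0 corresponds to flat dosing, 0.75 to the
# conventional allometric rule.

#' Allometrically scaled renal clearance
#'
#' Extrapolates the normal-weight clearance to a heavier subject with a
#' bodyweight power law:
#' `scaled_clr = clr_normal * (bw_obese / bw_normal)^exponent`.
#'
#' @param clr_normal Normal-weight clearance, L/h, > 0.
#' @param bw_normal,bw_obese Bodyweights, kg, > 0.
#' @param exponent Allometric exponent (0 = flat dosing, 0.75 = AS0.75).
#' @return Scaled clearance, L/h.
#' @examples
#' scaled_clr(10, 59.2, 118.3, 0.75)
#' @export
scaled_clr <- function(clr_normal, bw_normal, bw_obese, exponent) {
  if (any(clr_normal <= 0)) abort("`clr_normal` must be positive.")
  if (any(bw_normal <= 0) || any(bw_obese <= 0)) {
    abort("bodyweights must be positive.")
  }
  clr_normal * (bw_obese / bw_normal)^exponent
}

#' Signed prediction error of a scaled clearance
#'
#' `PE(%) = 100 * (scaled - pbpk) / pbpk`, with the PBPK-predicted clearance
#' taken as the true value.
#'
#' @param scaled Scaled clearance, L/h.
#' @param pbpk PBPK-predicted clearance, L/h, > 0.
#' @return Signed percentage error.
#' @export
prediction_error <- function(scaled, pbpk) {
  if (any(pbpk <= 0)) abort("`pbpk` clearance must be positive.")
  100 * (scaled - pbpk) / pbpk
}

#' Allometric exponent required for exact scaling
#'
#' The unique exponent for which the bodyweight power law reproduces the
#' PBPK clearance:
#' `exponent = ln(clr_obese / clr_normal) / ln(bw_obese / bw_normal)`.
#'
#' @param clr_obese,clr_normal Clearances, L/h, > 0.
#' @param bw_obese,bw_normal Bodyweights, kg, > 0 and distinct.
#' @return Dimensionless exponent.
#' @examples
#' required_exponent(15, 10, 177.5, 59.2)
#' @export
required_exponent <- function(clr_obese, clr_normal, bw_obese, bw_normal) {
  if (any(clr_obese <= 0) || any(clr_normal <= 0)) {
    abort("clearances must be positive.")
  }
  if (any(bw_obese <= 0) || any(bw_normal <= 0)) {
    abort("bodyweights must be positive.")
  }
  if (any(bw_obese == bw_normal)) {
    abort("`bw_obese` must differ from `bw_normal` (log of a unit weight ratio).")
  }
  log(clr_obese / clr_normal) / log(bw_obese / bw_normal)
}

#' Evaluate allometric scaling over a clearance table
#'
#' For every non-baseline row of a [renal_clearance()] table and every
#' requested exponent, computes the scaled clearance from the same drug's
#' normal-weight clearance (baseline BMI, rTA = 1), the signed prediction
#' error against the PBPK clearance, an accuracy flag, and the exponent that
#' would scale exactly.
#'
#' @param clearance A tibble from [renal_clearance()] (must include the
#'   baseline BMI rows at rTA = 1).
#' @param exponents Numeric vector of exponents; default `c(0, 0.75)`.
#' @param baseline_bmi BMI of the normal-weight reference, default 20.
#' @param pe_threshold Accuracy threshold on `|PE|` in percent (inclusive),
#'   default 30.
#'
#' @return A tibble with the drug/scenario identifier columns plus
#'   `exponent`, `scaled_clr`, `pbpk_clr`, `prediction_error`, `accurate`
#'   and `required_exponent`.
#' @export
evaluate_scaling <- function(clearance, exponents = c(0, 0.75),
                             baseline_bmi = 20, pe_threshold = 30) {
  if (length(exponents) == 0) abort("`exponents` must be non-empty.")
  base <- clearance %>%
    filter(.data$bmi == baseline_bmi, .data$rta == 1) %>%
    select("fu_normal_weight", "kp", "clint_ats", "binding_protein",
           clr_normal = "clr", bw_normal = "bodyweight")
  if (nrow(base) == 0) {
    abort("`clearance` contains no baseline rows (baseline BMI at rTA = 1).")
  }
  obese <- clearance %>%
    filter(.data$bmi != baseline_bmi) %>%
    select("fu_normal_weight", "kp", "clint_ats", "binding_protein",
           "bmi", "rta", "bodyweight", "clr") %>%
    left_join(base, by = c("fu_normal_weight", "kp", "clint_ats",
                           "binding_protein"))
  obese %>%
    cross_join(tibble(exponent = as.numeric(exponents))) %>%
    mutate(
      scaled_clr = scaled_clr(.data$clr_normal, .data$bw_normal,
                              .data$bodyweight, .data$exponent),
      pbpk_clr = .data$clr,
      prediction_error = prediction_error(.data$scaled_clr, .data$pbpk_clr),
      accurate = abs(.data$prediction_error) <= pe_threshold,
      required_exponent = required_exponent(.data$pbpk_clr, .data$clr_normal,
                                            .data$bodyweight, .data$bw_normal)
    ) %>%
    select("fu_normal_weight", "kp", "clint_ats", "binding_protein",
           "bmi", "rta", "exponent", "scaled_clr", "pbpk_clr",
           "prediction_error", "accurate", "required_exponent")
}

#' Classify systematic scaling accuracy per stratum
#'
#' A stratum (by default BMI x rTA x binding protein) and exponent is
#' "systematically accurate" if and only if every drug in it is scaled with
#' `|PE|` at or below the threshold.
#'
#' @param scaling A tibble from [evaluate_scaling()].
#' @param strata Character vector of grouping columns; default
#'   `c("bmi", "rta", "binding_protein")`. Any columns of `scaling` may be
#'   used (e.g. add `fu_normal_weight` or `clint_ats` bands).
#' @param pe_threshold Accuracy threshold on `|PE|` in percent (inclusive),
#'   default 30.
#'
#' @return A tibble with one row per stratum x exponent: the stratum
#'   columns, `exponent`, `n_drugs`, `max_abs_pe` and logical
#'   `systematically_accurate`.
#' @export
classify_systematic_accuracy <- function(scaling,
                                         strata = c("bmi", "rta",
                                                    "binding_protein"),
                                         pe_threshold = 30) {
  missing <- setdiff(strata, names(scaling))
  if (length(missing) > 0) {
    abort(paste0("stratum column(s) not in `scaling`: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(scaling) == 0) abort("`scaling` is empty.")
  scaling %>%
    group_by(across(dplyr::all_of(c(strata, "exponent")))) %>%
    summarise(
      n_drugs = n(),
      max_abs_pe = max(abs(.data$prediction_error)),
      systematically_accurate = all(abs(.data$prediction_error) <=
                                      pe_threshold),
      .groups = "drop"
    )
}

#' Range of exponents required for exact scaling
#'
#' Extrema of the per-row required exponent, optionally per group (e.g.
#' `by = "bmi"` for the per-BMI ranges). Filter the scaling table first to
#' restrict the scenario space (e.g. `rta == 1` or one binding protein).
#'
#' @param scaling A tibble from [evaluate_scaling()] (or any table with a
#'   `required_exponent` column).
#' @param by Optional character vector of grouping columns.
#'
#' @return A tibble with `min_exponent`, `max_exponent`, `range_width` and
#'   `n` per group (one row if `by` is `NULL`).
#' @export
summarize_exponent_range <- function(scaling, by = NULL) {
  if (nrow(scaling) == 0) abort("`scaling` selection is empty.")
  grouped <- if (is.null(by)) scaling else
    group_by(scaling, across(dplyr::all_of(by)))
  grouped %>%
    summarise(
      min_exponent = min(.data$required_exponent),
      max_exponent = max(.data$required_exponent),
      range_width = .data$max_exponent - .data$min_exponent,
      n = n(),
      .groups = "drop"
    )
}
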
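# ggplot2 views of the study results. These mirror the usual displays of
# this kind of sensitivity analysis: physiology change vs BMI, relative
# clearance vs BMI per transporter-activity scenario, and prediction-error
# panels per scaling exponent.

#' Plot obesity-induced physiology changes relative to normal weight
#'
#' Line plot of each system parameter's ratio to the normal-weight baseline
#' across BMI.
#'
#' @param subjects A tibble from [make_subjects()].
#' @param baseline_bmi Baseline BMI, default 20.
#' @return A ggplot.
#' @export
plot_physiology <- function(subjects, baseline_bmi = 20) {
  rel <- relative_parameters(subjects, baseline_bmi) %>%
    filter(!.data$parameter %in% c("ptcpgk"))
  ggplot2::ggplot(rel, ggplot2::aes(x = .data$bmi, y = .data$ratio,
                                    colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = expression(BMI ~ (kg/m^2)),
                  y = "value relative to normal weight",
                  colour = "parameter") +
    ggplot2::theme_minimal()
}

#' Plot relative renal clearance across BMI
#'
#' Relative CLr (percent of the normal-weight value) versus BMI, one line per
#' relative transporter activity, faceted by unbound fraction and binding
#' protein; the +/-30% band (70--130%) is marked. To keep panels readable the
#' plot subsets to a single Kp (default 1) and, when more than three CLint_ATS
#' values are present, to the lowest, an intermediate and the highest.
#'
#' @param study A `clr_study` from [run_study()].
#' @param kp Kp value to display, default 1 (falls back to the value closest
#'   to 1 present in the grid).
#' @return A ggplot.
#' @export
plot_relative_clearance <- function(study, kp = 1) {
  cl <- study$clearance
  kp_use <- cl$kp[which.min(abs(cl$kp - kp))]
  dat <- cl %>%
    filter(.data$kp == kp_use, !is.na(.data$relative_clr))
  ci <- sort(unique(dat$clint_ats))
  if (length(ci) > 3) {
    keep <- ci[c(1, ceiling(length(ci) / 2), length(ci))]
    dat <- filter(dat, .data$clint_ats %in% keep)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bmi, y = .data$relative_clr,
                                    colour = factor(.data$rta),
                                    linetype = factor(round(.data$clint_ats)))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(70, 130), linetype = "dashed",
                        colour = "grey30") +
    ggplot2::facet_grid(ggplot2::vars(.data$binding_protein),
                        ggplot2::vars(.data$fu_normal_weight),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(BMI ~ (kg/m^2)),
                  y = "relative CLr (% of normal weight)",
                  colour = "rTA", linetype = "CLint_ATS") +
    ggplot2::theme_minimal()
}

#' Plot scaling prediction errors
#'
#' Signed prediction error of the scaled clearance against the PBPK value
#' versus BMI, per exponent and binding protein, with the +/-30% accuracy
#' band. Subsets to a single Kp like [plot_relative_clearance()].
#'
#' @inheritParams plot_relative_clearance
#' @return A ggplot.
#' @export
plot_prediction_error <- function(study, kp = 1) {
  sc <- study$scaling
  kp_use <- sc$kp[which.min(abs(sc$kp - kp))]
  dat <- filter(sc, .data$kp == kp_use)
  ci <- sort(unique(dat$clint_ats))
  if (length(ci) > 3) {
    keep <- ci[c(1, ceiling(length(ci) / 2), length(ci))]
    dat <- filter(dat, .data$clint_ats %in% keep)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bmi,
                                    y = .data$prediction_error,
                                    colour = factor(.data$rta),
                                    group = interaction(.data$rta,
                                                        .data$fu_normal_weight,
                                                        .data$clint_ats))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-30, 30), linetype = "dotted") +
    ggplot2::facet_grid(ggplot2::vars(.data$exponent),
                        ggplot2::vars(.data$binding_protein),
                        labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(-100, 100)) +
    ggplot2::labs(x = expression(BMI ~ (kg/m^2)),
                  y = "prediction error (%)", colour = "rTA") +
    ggplot2::theme_minimal()
}

#' @rdname run_study
#' @param object A `clr_study`.
#' @param type Plot type: `"relative_clr"`, `"prediction_error"` or
#'   `"physiology"`.
#' @method autoplot clr_study
#' @export
autoplot.clr_study <- function(object, type = c("relative_clr",
                                                "prediction_error",
                                                "physiology"), ...) {
  type <- arg_match(type)
  switch(type,
         relative_clr = plot_relative_clearance(object),
         prediction_error = plot_prediction_error(object),
         physiology = plot_physiology(object$subjects,
                                      object$config$baseline_bmi))
}
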
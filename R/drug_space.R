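# The study has no external data: its input is a full factorial grid of
# hypothetical drugs (fu, Kp, CLint_ATS, binding protein) crossed with
# scenarios (BMI category, relative transporter activity).

#' Default factorial axes of the hypothetical drug space
#'
#' Returns the study's default value lists for every grid axis:
#' * `fu_normal_weight`: unbound plasma fraction in the normal-weight subject
#'   (0.05, 0.25, 0.50, 0.75, 0.95, 1.00);
#' * `kp`: blood-cell partition coefficient
#'   (0.35, 1, 2, 3, 4, 5, 10, 20, 30, 40);
#' * `clint_ats`: intrinsic active-secretion clearance, ul/min per mg
#'   protein — 32 arithmetically equidistant values from 2 to 500
#'   (step 498/31);
#' * `rta`: relative transporter activity as a fraction of normal-weight
#'   activity (0.2, 0.5, 1, 1.5, 2, 2.5);
#' * `bmi`: subject categories 20, 25, 30, 40, 50, 60 kg/m^2;
#' * `binding_protein`: `"HSA"`, `"AAG"`.
#'
#' @return Named list of ordered value vectors.
#' @examples
#' lengths(default_grid_values())
#' @export
default_grid_values <- function() {
  list(
    fu_normal_weight = c(0.05, 0.25, 0.50, 0.75, 0.95, 1.00),
    kp = c(0.35, 1, 2, 3, 4, 5, 10, 20, 30, 40),
    clint_ats = seq(2, 500, length.out = 32),
    rta = c(0.2, 0.5, 1, 1.5, 2, 2.5),
    bmi = c(20, 25, 30, 40, 50, 60),
    binding_protein = c("HSA", "AAG")
  )
}

.validate_grid_axis <- function(grid, axis) {
  if (!axis %in% names(grid)) {
    abort(paste0("axis `", axis, "` is not present in the grid definition."))
  }
  v <- grid[[axis]]
  if (length(v) == 0) abort(paste0("axis `", axis, "` is empty."))
  if (axis == "fu_normal_weight" && (any(v <= 0) || any(v > 1))) {
    abort("`fu_normal_weight` values must lie in (0, 1].")
  }
  if (axis %in% c("kp", "clint_ats", "rta", "bmi") && any(v <= 0)) {
    abort(paste0("`", axis, "` values must be positive."))
  }
  if (axis == "binding_protein" && !all(v %in% c("HSA", "AAG"))) {
    abort("`binding_protein` values must be \"HSA\" or \"AAG\".")
  }
  invisible(v)
}

#' Enumerate the factorial drug/scenario combinations
#'
#' Full Cartesian product of the requested axes, in deterministic
#' lexicographic order: the first axis varies slowest and the last axis
#' fastest, so repeated runs produce byte-identical tables. With the default
#' four axes (fu, Kp, CLint_ATS, rTA) this yields the study's 11,520
#' parameter combinations; the binding-protein dimension is handled as two
#' parallel runs of the same grid.
#'
#' @param grid Named list of axis values, e.g. [default_grid_values()].
#' @param axes Character vector of axis names to cross, slowest first.
#'
#' @return A tibble with one column per axis and one row per combination.
#' @examples
#' nrow(enumerate_combinations()) # 11520
#' @export
enumerate_combinations <- function(grid = default_grid_values(),
                                   axes = c("fu_normal_weight", "kp",
                                            "clint_ats", "rta")) {
  vals <- lapply(axes, function(a) .validate_grid_axis(grid, a))
  names(vals) <- axes
  out <- rlang::exec(tidyr::expand_grid, !!!vals)
  as_tibble(out)
}

#' Enumerate hypothetical drugs
#'
#' The drug axes only (fu, Kp, CLint_ATS crossed with binding protein),
#' without scenario axes. Each row is one hypothetical drug.
#'
#' @inheritParams enumerate_combinations
#' @return A tibble with columns `fu_normal_weight`, `kp`, `clint_ats`,
#'   `binding_protein`.
#' @export
drug_grid <- function(grid = default_grid_values()) {
  enumerate_combinations(grid, axes = c("binding_protein", "fu_normal_weight",
                                        "kp", "clint_ats")) %>%
    relocate("fu_normal_weight", "kp", "clint_ats", "binding_protein")
}

#' Enumerate scenarios
#'
#' A scenario is one (BMI category, relative transporter activity) pairing
#' applied to a drug.
#'
#' @inheritParams enumerate_combinations
#' @return A tibble with columns `bmi`, `rta`.
#' @export
scenario_grid <- function(grid = default_grid_values()) {
  enumerate_combinations(grid, axes = c("bmi", "rta"))
}
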
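# Plain-text (YAML) configuration: run configurations and physiology
# parameter sets are both loadable from small YAML files so a study is fully
# described by text.

#' Build a run configuration
#'
#' Collects every tunable of the study pipeline with the study defaults:
#' six BMI categories at height 1.72 m, the full factorial drug grid, both
#' binding proteins, exponents 0 (flat dosing) and 0.75, and the inclusive
#' +/-30% prediction-error accuracy threshold.
#'
#' @param physiology_set Name of a registered physiology set (or a
#'   `physiology_set` object). Default `"fixture_linear"`.
#' @param height Subject height, m.
#' @param sex `"male"` or `"female"`.
#' @param bmi_categories BMI categories, kg/m^2; must contain
#'   `baseline_bmi`.
#' @param baseline_bmi Normal-weight reference BMI, default 20.
#' @param grid Named list of drug/scenario axis values; defaults to
#'   [default_grid_values()] with `bmi` replaced by `bmi_categories`.
#'   Partial lists override only the named axes.
#' @param exponents Allometric exponents to evaluate.
#' @param pe_threshold Accuracy threshold on `|PE|`, percent.
#' @param ptcpgk Proximal tubule cells per gram kidney.
#' @param output_dir Directory for the delimited output tables, or `NULL`
#'   to keep results in memory only.
#'
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(physiology_set = "fixture_linear",
                       height = 1.72,
                       sex = c("male", "female"),
                       bmi_categories = c(20, 25, 30, 40, 50, 60),
                       baseline_bmi = 20,
                       grid = list(),
                       exponents = c(0, 0.75),
                       pe_threshold = 30,
                       ptcpgk = 99.4,
                       output_dir = NULL) {
  sex <- arg_match(sex)
  full_grid <- modifyList(default_grid_values(), as.list(grid))
  full_grid$bmi <- as.numeric(bmi_categories)
  if (!baseline_bmi %in% bmi_categories) {
    abort("`bmi_categories` must include `baseline_bmi`.")
  }
  if (pe_threshold <= 0) abort("`pe_threshold` must be positive.")
  if (length(exponents) == 0) abort("`exponents` must be non-empty.")
  for (a in names(full_grid)) .validate_grid_axis(full_grid, a)
  structure(
    list(
      physiology_set = physiology_set,
      height = height,
      sex = sex,
      bmi_categories = as.numeric(bmi_categories),
      baseline_bmi = baseline_bmi,
      grid = full_grid,
      exponents = as.numeric(exponents),
      pe_threshold = pe_threshold,
      ptcpgk = ptcpgk,
      output_dir = output_dir
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  nm <- if (inherits(x$physiology_set, "physiology_set"))
    x$physiology_set$name else x$physiology_set
  cat("<run_config>\n")
  cat("  physiology:", nm, "| sex:", x$sex, "| height:", x$height, "m\n")
  cat("  BMI categories:", paste(x$bmi_categories, collapse = ", "),
      "(baseline", paste0(x$baseline_bmi, ")"), "\n")
  cat("  drug grid:", length(x$grid$fu_normal_weight), "fu x",
      length(x$grid$kp), "Kp x", length(x$grid$clint_ats), "CLint_ATS x",
      length(x$grid$rta), "rTA;",
      paste(x$grid$binding_protein, collapse = "/"), "\n")
  cat("  exponents:", paste(x$exponents, collapse = ", "),
      "| PE threshold: +/-", x$pe_threshold, "%\n")
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' The file is a flat mapping of [run_config()] arguments; axis lists go
#' under a `grid:` mapping. The CLint_ATS axis may be given either as an
#' explicit list or as `{from, to, length}` for an equidistant sequence.
#' See `system.file("extdata", "default_config.yaml", package =
#' "renalscale")` for a complete example.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$grid$clint_ats) && is.list(raw$grid$clint_ats)) {
    sp <- raw$grid$clint_ats
    raw$grid$clint_ats <- seq(sp$from, sp$to, length.out = sp$length)
  }
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  rlang::exec(run_config, !!!args)
}

#' Load a physiology parameter set from a YAML file
#'
#' Each entry of the `parameters:` mapping defines one system parameter in
#' canonical units (L/h, g, g/L, fraction) in one of four forms:
#' * `value: <number>` — a constant;
#' * `male: <number>` / `female: <number>` — a sex-specific constant
#'   (e.g. hematocrit);
#' * `intercept`, `slope`, `ref_bodyweight` — linear in bodyweight:
#'   `intercept + slope * (bodyweight - ref_bodyweight)`;
#' * `expr: "<R expression>"` — an arbitrary deterministic expression in the
#'   variables `bmi`, `bodyweight` and `sex`, for transcribing published
#'   equations.
#'
#' @param path Path to the YAML file (top-level keys `name`, optional
#'   `reference`, and `parameters`).
#' @param register Register the set under its name so [physiology_set()]
#'   can find it. Default `TRUE`.
#' @param overwrite Passed to [register_physiology_set()].
#' @return The `physiology_set`, invisibly if registered.
#' @export
physiology_set_from_config <- function(path, register = TRUE,
                                       overwrite = FALSE) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$name) || is.null(raw$parameters)) {
    abort("physiology config must have top-level `name` and `parameters`.")
  }
  fns <- lapply(raw$parameters, .physiology_fn_from_spec)
  set <- new_physiology_set(raw$name, fns, reference = raw$reference %||% path)
  if (register) {
    register_physiology_set(set, overwrite = overwrite)
    return(invisible(set))
  }
  set
}

.physiology_fn_from_spec <- function(spec) {
  if (!is.null(spec$expr)) {
    e <- parse(text = spec$expr)[[1]]
    return(function(bmi, sex, bodyweight) {
      eval(e, list(bmi = bmi, sex = sex, bodyweight = bodyweight))
    })
  }
  if (!is.null(spec$value)) {
    v <- spec$value
    return(function(bmi, sex, bodyweight) rep_len(v, length(bmi)))
  }
  if (!is.null(spec$male) && !is.null(spec$female)) {
    m <- spec$male; f <- spec$female
    return(function(bmi, sex, bodyweight) {
      rep_len(ifelse(sex == "female", f, m), length(bmi))
    })
  }
  if (!is.null(spec$intercept) && !is.null(spec$slope)) {
    a <- spec$intercept; b <- spec$slope; w0 <- spec$ref_bodyweight %||% 0
    return(function(bmi, sex, bodyweight) a + b * (bodyweight - w0))
  }
  abort("unrecognised physiology parameter specification in config.")
}
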
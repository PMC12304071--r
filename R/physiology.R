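#' Bodyweight from body mass index
#'
#' Converts BMI (kg/m^2) and height (m) to total bodyweight (kg) via
#' `bmi * height^2`. Typical subjects in the simulation study are defined by
#' BMI at a fixed height of 1.72 m, the adult median height, so bodyweight is
#' always a derived quantity, never an independent input.
#'
#' @param bmi Body mass index, kg/m^2. Vectorised.
#' @param height Body height in metres. Default 1.72.
#' @param digits Decimal places for the reported weight. The study tables
#'   print weights to one decimal (the default); pass `NULL` for the exact
#'   unrounded value, which is what the physiology functions use internally.
#'
#' @return Numeric vector of bodyweights in kg.
#' @examples
#' bodyweight_from_bmi(c(20, 25, 30, 40, 50, 60))
#' @export
bodyweight_from_bmi <- function(bmi, height = 1.72, digits = 1) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort("`bmi` must be finite and positive.")
  }
  if (any(!is.finite(height)) || any(height <= 0)) {
    abort("`height` must be finite and positive.")
  }
  bw <- bmi * height^2
  if (!is.null(digits)) bw <- round(bw, digits)
  bw
}

# ---- physiology parameter sets -----------------------------------------

#' Create a physiology parameter set
#'
#' A physiology parameter set maps BMI (together with sex and the derived
#' bodyweight) to the system parameters that drive the renal clearance model:
#' glomerular filtration rate (`gfr`, L/h), renal blood flow (`qr`, L/h),
#' total kidney weight (`kidney_weight`, g), plasma concentrations of human
#' serum albumin (`hsa_conc`, g/L) and alpha-1 acid glycoprotein
#' (`aag_conc`, g/L), and `hematocrit` (volume fraction). Each entry of
#' `fns` is a function of `(bmi, sex, bodyweight)` returning the value in
#' those canonical units; all functions must be deterministic and defined on
#' BMI 20--60.
#'
#' @param name Identifier, e.g. `"fixture_linear"`.
#' @param fns Named list of functions, one per parameter above.
#' @param reference Free-text provenance of the equations.
#'
#' @return An object of class `physiology_set`.
#' @seealso [physiology_set()], [physiology_set_from_config()],
#'   [make_subjects()]
#' @export
new_physiology_set <- function(name, fns, reference = "") {
  required <- c("gfr", "qr", "kidney_weight", "hsa_conc", "aag_conc",
                "hematocrit")
  missing <- setdiff(required, names(fns))
  if (length(missing) > 0) {
    abort(paste0("physiology set `", name, "` is missing parameter function(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(vapply(fns, is.function, logical(1)))) {
    abort("every element of `fns` must be a function of (bmi, sex, bodyweight).")
  }
  structure(
    list(name = name, fns = fns[required], reference = reference),
    class = "physiology_set"
  )
}

#' @export
print.physiology_set <- function(x, ...) {
  cat("<physiology_set> ", x$name, "\n", sep = "")
  cat("  parameters: ", paste(names(x$fns), collapse = ", "), "\n", sep = "")
  if (nzchar(x$reference)) cat("  reference: ", x$reference, "\n", sep = "")
  invisible(x)
}

.physiology_registry <- new.env(parent = emptyenv())

#' Register a physiology parameter set by name
#'
#' Registered sets can subsequently be retrieved with [physiology_set()] and
#' referenced by name in run configurations.
#'
#' @param set A [new_physiology_set()] object.
#' @param overwrite Replace an existing set of the same name.
#' @return The set, invisibly.
#' @export
register_physiology_set <- function(set, overwrite = FALSE) {
  stopifnot(inherits(set, "physiology_set"))
  if (!overwrite && exists(set$name, envir = .physiology_registry)) {
    abort(paste0("physiology set `", set$name, "` is already registered; ",
                 "use `overwrite = TRUE` to replace it."))
  }
  assign(set$name, set, envir = .physiology_registry)
  invisible(set)
}

#' Retrieve a physiology parameter set
#'
#' @param name Name of a registered set (see [physiology_sets()]), or a
#'   `physiology_set` object, which is returned unchanged.
#'
#' @details The built-in `"fixture_linear"` set is a simple synthetic set
#' with linear bodyweight dependence that reproduces the qualitative
#' obesity trends (GFR, renal blood flow, kidney weight and AAG rise with
#' BMI; HSA falls; hematocrit depends on sex only). The name
#' `"berton2022"` is reserved for the published BMI-dependent equations of
#' Berton and colleagues; their coefficients are not distributed with this
#' package and must be transcribed from the original publication and loaded
#' with [physiology_set_from_config()] (or registered directly) before that
#' name can be used.
#'
#' @return A `physiology_set`.
#' @export
physiology_set <- function(name) {
  if (inherits(name, "physiology_set")) return(name)
  stopifnot(is.character(name), length(name) == 1)
  if (exists(name, envir = .physiology_registry)) {
    return(get(name, envir = .physiology_registry))
  }
  if (identical(name, "berton2022")) {
    abort(paste0(
      "physiology set `berton2022` is not bundled: its BMI-dependent ",
      "parameter equations must be transcribed from the original ",
      "publication (Berton et al.) and loaded with ",
      "`physiology_set_from_config()` or `register_physiology_set()`."
    ))
  }
  abort(paste0("unknown physiology set `", name, "`; registered sets: ",
               paste(physiology_sets(), collapse = ", ")))
}

#' List registered physiology set names
#' @return Character vector of names.
#' @export
physiology_sets <- function() {
  sort(ls(envir = .physiology_registry))
}

# Baseline bodyweight anchoring the fixture's linear equations (BMI 20 at
# 1.72 m, reported to one decimal).
.fixture_bw0 <- 59.2

fixture_linear_set <- function() {
  new_physiology_set(
    name = "fixture_linear",
    fns = list(
      gfr           = function(bmi, sex, bodyweight) 6.5 + 0.04 * (bodyweight - .fixture_bw0),
      qr            = function(bmi, sex, bodyweight) 60 + 0.25 * (bodyweight - .fixture_bw0),
      kidney_weight = function(bmi, sex, bodyweight) 300 + 1.5 * (bodyweight - .fixture_bw0),
      hsa_conc      = function(bmi, sex, bodyweight) 45 - 0.03 * (bodyweight - .fixture_bw0),
      aag_conc      = function(bmi, sex, bodyweight) 0.8 + 0.004 * (bodyweight - .fixture_bw0),
      hematocrit    = function(bmi, sex, bodyweight) ifelse(sex == "female", 0.40, 0.45)
    ),
    reference = "synthetic linear fixture (not from literature)"
  )
}

.ensure_builtin_sets <- function() {
  if (!exists("fixture_linear", envir = .physiology_registry)) {
    register_physiology_set(fixture_linear_set())
  }
}

.onLoad <- function(libname, pkgname) {
  .ensure_builtin_sets()
}

# ---- subjects ----------------------------------------------------------

#' Generate virtual-subject physiology profiles
#'
#' Builds one typical (deterministic) virtual subject per BMI value: the
#' bodyweight is derived from BMI and height, and every system parameter is
#' computed by the chosen physiology parameter set. Proximal tubule cellularity
#' per gram kidney (PTCPGK) is treated as BMI-invariant.
#'
#' @param bmi Numeric vector of BMI values, kg/m^2. The study default is
#'   `c(20, 25, 30, 40, 50, 60)`. Values outside 20--60 trigger a warning
#'   (the parameter equations are only intended for that range).
#' @param height Height in metres, default 1.72.
#' @param sex `"male"` (default) or `"female"`.
#' @param params A `physiology_set` or the name of a registered one.
#' @param ptcpgk Proximal tubule cells per gram kidney; default 99.4.
#'
#' @return A tibble with one row per BMI and columns `bmi`, `height`, `sex`,
#'   `bodyweight` (kg, unrounded), `gfr` (L/h), `qr` (L/h), `kidney_weight`
#'   (g), `hsa_conc` (g/L), `aag_conc` (g/L), `hematocrit` (fraction) and
#'   `ptcpgk`.
#' @examples
#' make_subjects(c(20, 40, 60))
#' @export
make_subjects <- function(bmi, height = 1.72, sex = c("male", "female"),
                          params = "fixture_linear", ptcpgk = 99.4) {
  .ensure_builtin_sets()
  sex <- arg_match(sex)
  if (any(!is.finite(bmi)) || any(bmi <= 0)) abort("`bmi` must be finite and positive.")
  if (!is.finite(height) || height <= 0) abort("`height` must be finite and positive.")
  if (any(bmi < 20 | bmi > 60)) {
    warn("BMI value(s) outside [20, 60]: physiology equations are extrapolated.")
  }
  set <- physiology_set(params)
  bw <- bodyweight_from_bmi(bmi, height, digits = NULL)
  vals <- lapply(set$fns, function(f) {
    v <- f(bmi, sex, bw)
    rep_len(as.numeric(v), length(bmi))
  })
  out <- tibble(
    bmi = as.numeric(bmi), height = height, sex = sex, bodyweight = bw,
    gfr = vals$gfr, qr = vals$qr, kidney_weight = vals$kidney_weight,
    hsa_conc = vals$hsa_conc, aag_conc = vals$aag_conc,
    hematocrit = vals$hematocrit, ptcpgk = ptcpgk
  )
  for (p in c("gfr", "qr", "kidney_weight", "hsa_conc", "aag_conc")) {
    if (any(!is.finite(out[[p]])) || any(out[[p]] <= 0)) {
      abort(paste0("physiology set `", set$name, "` produced a non-positive ",
                   "or non-finite value for `", p, "`."))
    }
  }
  if (any(out$hematocrit <= 0 | out$hematocrit >= 1)) {
    abort(paste0("physiology set `", set$name,
                 "` produced `hematocrit` outside (0, 1)."))
  }
  out
}

#' Physiology parameters relative to the normal-weight subject
#'
#' Expresses each subject's system parameters as a ratio to the normal-weight
#' baseline subject (BMI 20 by convention) from the same table, mirroring the
#' usual "relative to normal weight" display of obesity-induced physiological
#' change.
#'
#' @param subjects A tibble from [make_subjects()].
#' @param baseline_bmi BMI of the baseline row; default 20. Must be present
#'   in `subjects`.
#'
#' @return A long tibble with columns `bmi`, `parameter`, `value`,
#'   `baseline` and `ratio` (= value / baseline; exactly 1 for the baseline
#'   row).
#' @export
relative_parameters <- function(subjects, baseline_bmi = 20) {
  pars <- c("bodyweight", "gfr", "qr", "kidney_weight", "hsa_conc",
            "aag_conc", "hematocrit", "ptcpgk")
  base <- subjects[subjects$bmi == baseline_bmi, , drop = FALSE]
  if (nrow(base) != 1) {
    abort(paste0("`subjects` must contain exactly one row with bmi = ",
                 baseline_bmi, " to serve as baseline."))
  }
  long <- tidyr::pivot_longer(subjects[, c("bmi", pars)], -"bmi",
                              names_to = "parameter", values_to = "value")
  base_long <- tibble(parameter = pars,
                      baseline = as.numeric(base[1, pars]))
  if (any(base_long$baseline == 0)) {
    abort("baseline subject has a zero-valued parameter; ratios are undefined.")
  }
  long %>%
    left_join(base_long, by = "parameter") %>%
    mutate(ratio = .data$value / .data$baseline)
}
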
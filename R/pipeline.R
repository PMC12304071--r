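# Orchestration of the full study: subjects -> drug grid -> clearance ->
# scaling evaluation -> systematic-accuracy verdicts, with optional
# delimited-table export. Everything is deterministic: identical
# configurations give byte-identical outputs.

#' Run the full renal-clearance scaling study
#'
#' Generates the virtual subjects, enumerates the factorial drug grid,
#' evaluates the PBPK clearance model for every drug x BMI x rTA x
#' binding-protein combination, evaluates allometric scaling for each
#' configured exponent, and classifies systematic accuracy per
#' BMI x rTA x binding-protein stratum. When `config$output_dir` is set, the
#' tables are written as CSV together with a run log.
#'
#' @param config A [run_config()].
#'
#' @return An object of class `clr_study`: a list with elements `config`,
#'   `subjects`, `drugs`, `clearance`, `scaling`, `verdicts` and
#'   `exponent_ranges` (per-BMI required-exponent extrema). Use [tidy()] to
#'   extract tables and [autoplot()] to visualise.
#' @examples
#' cfg <- run_config(grid = list(kp = 1, clint_ats = c(2, 50, 500)))
#' study <- run_study(cfg)
#' glance(study)
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  subjects <- make_subjects(config$bmi_categories, config$height, config$sex,
                            params = config$physiology_set,
                            ptcpgk = config$ptcpgk)
  drugs <- drug_grid(config$grid)
  clearance <- renal_clearance(subjects, drugs, rta = config$grid$rta,
                               baseline_bmi = config$baseline_bmi)
  scaling <- evaluate_scaling(clearance, exponents = config$exponents,
                              baseline_bmi = config$baseline_bmi,
                              pe_threshold = config$pe_threshold)
  verdicts <- classify_systematic_accuracy(scaling,
                                           pe_threshold = config$pe_threshold)
  exponent_ranges <- scaling %>%
    filter(.data$exponent == config$exponents[1]) %>%
    summarize_exponent_range(by = "bmi")

  study <- structure(
    list(config = config, subjects = subjects, drugs = drugs,
         clearance = clearance, scaling = scaling, verdicts = verdicts,
         exponent_ranges = exponent_ranges),
    class = "clr_study"
  )
  if (!is.null(config$output_dir)) {
    write_study_tables(study, config$output_dir)
  }
  study
}

#' Write the study tables as delimited files
#'
#' Writes `subjects.csv`, `drug_grid.csv`, `clearance.csv`, `scaling.csv`,
#' `verdicts.csv`, `exponent_ranges.csv` and a `run_log.txt` (configuration
#' echo, row counts, configuration hash) to `dir`. Output is UTF-8,
#' comma-delimited, '.' decimal, empty string for missing values; doubles are
#' printed at 6 significant digits unless `digits = NULL` (full precision).
#'
#' @param study A `clr_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @param digits Significant digits for doubles, default 6; `NULL` to keep
#'   full precision.
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(study, dir, digits = 6) {
  stopifnot(inherits(study, "clr_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(subjects = study$subjects, drug_grid = study$drugs,
                 clearance = study$clearance, scaling = study$scaling,
                 verdicts = study$verdicts,
                 exponent_ranges = study$exponent_ranges)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (!is.null(digits)) {
      tb <- mutate(tb, across(dplyr::where(is.double), ~ signif(.x, digits)))
    }
    readr::write_csv(tb, file.path(dir, paste0(nm, ".csv")), na = "")
  }
  log_lines <- c(
    paste0("renalscale run log"),
    paste0("config_hash: ", rlang::hash(study$config)),
    utils::capture.output(print(study$config)),
    paste0("rows_", names(tables), ": ",
           vapply(tables, nrow, integer(1)))
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.clr_study <- function(x, ...) {
  cat("<clr_study>\n")
  cat("  subjects:", nrow(x$subjects), "| drugs:", nrow(x$drugs),
      "| clearance rows:", nrow(x$clearance),
      "| scaling rows:", nrow(x$scaling), "\n")
  acc <- x$verdicts %>%
    group_by(.data$exponent) %>%
    summarise(accurate_strata = sum(.data$systematically_accurate),
              strata = n(), .groups = "drop")
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  exponent %.2f: %d / %d strata systematically accurate\n",
                acc$exponent[i], acc$accurate_strata[i], acc$strata[i]))
  }
  invisible(x)
}

#' @rdname run_study
#' @param x A `clr_study`.
#' @param table Which table `tidy()` should return.
#' @param ... Unused.
#' @method tidy clr_study
#' @export
tidy.clr_study <- function(x, table = c("clearance", "scaling", "verdicts",
                                        "subjects", "drugs",
                                        "exponent_ranges"), ...) {
  table <- arg_match(table)
  as_tibble(x[[table]])
}

#' @rdname run_study
#' @method glance clr_study
#' @export
glance.clr_study <- function(x, ...) {
  acc <- x$scaling %>%
    group_by(.data$exponent) %>%
    summarise(p = mean(.data$accurate), .groups = "drop")
  tibble(
    physiology_set = physiology_set(x$config$physiology_set)$name,
    n_subjects = nrow(x$subjects),
    n_drugs = nrow(x$drugs),
    n_clearance_rows = nrow(x$clearance),
    n_scaling_rows = nrow(x$scaling),
    prop_accurate_flat = acc$p[match(0, acc$exponent)],
    prop_accurate_as075 = acc$p[match(0.75, acc$exponent)],
    min_required_exponent = min(x$scaling$required_exponent),
    max_required_exponent = max(x$scaling$required_exponent)
  )
}
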
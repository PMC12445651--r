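#' Specification of one external-validation scenario
#'
#' The four validation scenarios exercised by the pipeline:
#' * `"i"` — At-biopsy model on the whole novel-therapy cohort;
#' * `"ii"` — At-biopsy model restricted to patients treated with ERAs,
#'   SGLT2 inhibitors or their combination only;
#' * `"iii"` — Post-biopsy model on 1-year landmark covariates;
#' * `"iv"` — Post-biopsy model with the novel drugs remapped onto the
#'   tool's historical drug variables (ERA/SGLT2i as RAS blockade; Nefecon,
#'   hydroxychloroquine, telitacicept as immunosuppression).
#'
#' @param scenario_id `"i"`, `"ii"`, `"iii"` or `"iv"`.
#' @param variant `"with_race"` or `"without_race"`.
#' @param horizon_months Risk horizon (default 60 months, the 5-year risk).
#' @param cohort_filter Optional predicate `function(cohort) -> logical`;
#'   scenario `"ii"` defaults to the ERA/SGLT2i-only filter.
#' @return A list of class `iigan_scenario_spec` with fields `scenario_id`,
#'   `model_id`, `variant`, `cohort_filter`, `drug_remap`,
#'   `landmark_months`, `horizon_months`.
#' @export
scenario_spec <- function(scenario_id = c("i", "ii", "iii", "iv"),
                          variant = c("with_race", "without_race"),
                          horizon_months = 60,
                          cohort_filter = NULL) {
  scenario_id <- match.arg(scenario_id)
  variant <- match.arg(variant)
  spec <- switch(scenario_id,
    i = list(model_id = "at_biopsy", drug_remap = FALSE, landmark_months = 0),
    ii = list(model_id = "at_biopsy", drug_remap = FALSE, landmark_months = 0),
    iii = list(model_id = "post_biopsy", drug_remap = FALSE, landmark_months = 12),
    iv = list(model_id = "post_biopsy", drug_remap = TRUE, landmark_months = 12)
  )
  if (scenario_id == "ii" && is.null(cohort_filter)) {
    cohort_filter <- era_sglt2i_only
  }
  structure(
    c(
      list(
        scenario_id = scenario_id, variant = variant,
        horizon_months = horizon_months, cohort_filter = cohort_filter
      ),
      spec
    ),
    class = "iigan_scenario_spec"
  )
}

#' @rdname scenario_spec
#' @param cohort A cohort tibble with the five novel-drug flag columns.
#' @export
era_sglt2i_only <- function(cohort) {
  (cohort$novel_era | cohort$novel_sglt2i) &
    !cohort$novel_nefecon & !cohort$novel_hcq & !cohort$novel_telitacicept
}

#' Run one external-validation scenario end-to-end
#'
#' Applies the scenario's filter and drug remapping to a copy of the cohort,
#' shifts the time origin to the landmark for the Post-biopsy scenarios,
#' computes linear predictors and horizon risks from the coefficient set,
#' assigns percentile risk groups, and produces the full
#' [validation report][validate_predictions] (optionally with adjusted eGFR
#' slopes when trajectories are supplied).
#'
#' @param cohort Cohort tibble (see [generate_cohort()] for columns).  The
#'   input is never mutated.
#' @param spec An [`iigan_scenario_spec`][scenario_spec].
#' @param coeffs Coefficient set; defaults to the synthetic-reference set
#'   matching the scenario's `model_id` and `variant`.
#' @param trajectories Optional long-format eGFR records for the slope
#'   analysis.
#' @param quiet Suppress the scenario log line.
#' @return An `iigan_validation` report; when trajectories are supplied it
#'   carries an additional `slopes` element.
#' @export
run_scenario <- function(cohort, spec = scenario_spec("i"), coeffs = NULL,
                         trajectories = NULL, quiet = FALSE) {
  stopifnot(inherits(spec, "iigan_scenario_spec"))
  if (is.null(coeffs)) {
    coeffs <- iigan_coefficient_set(
      paste0("synthetic_reference_", spec$model_id), spec$variant
    )
  }
  if (coeffs$model_id != spec$model_id) {
    abort("coefficient set model_id does not match the scenario")
  }
  data <- tibble::as_tibble(cohort)
  n_input <- nrow(data)
  if (spec$drug_remap) data <- remap_novel_drugs(data)
  if (!is.null(spec$cohort_filter)) {
    keep <- spec$cohort_filter(data)
    data <- data[keep, ]
  }
  if (spec$landmark_months > 0) {
    needed <- c("egfr_12m", "proteinuria_12m", "map_12m", "complete_12m")
    if (!all(needed %in% names(data))) {
      abort(sprintf(
        "scenario (%s) needs landmark covariates: %s",
        spec$scenario_id,
        paste(setdiff(needed, names(data)), collapse = ", ")
      ))
    }
    data <- data[data$complete_12m &
      data$followup_months > spec$landmark_months, ]
    data$followup_months <- data$followup_months - spec$landmark_months
  }
  if (nrow(data) < 20) abort("fewer than 20 patients after filtering")
  data <- add_risk_predictions(data, coeffs,
    horizon_months = spec$horizon_months
  ) |>
    assign_risk_groups()
  if (!quiet) {
    rlang::inform(sprintf(
      "scenario %s [%s/%s, %s]: n = %d (of %d), events = %d, horizon = %g m",
      spec$scenario_id, spec$model_id, spec$variant, coeffs$label,
      nrow(data), n_input, sum(data$event), spec$horizon_months
    ))
  }
  report <- validate_predictions(
    data,
    scenario_id = sprintf("%s_%s_%s", spec$scenario_id, spec$model_id, spec$variant),
    horizon_months = spec$horizon_months
  )
  if (!is.null(trajectories)) {
    report$slopes <- fit_egfr_slopes(trajectories, data)
  }
  report
}

#' Baseline characteristics table
#'
#' Medians with interquartile ranges for continuous covariates and counts
#' with one-decimal half-up percentages for categorical ones, in the style
#' of a clinical baseline table, plus the composite-outcome summary.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `characteristic`, `n`, `pct`, `median`,
#'   `q1`, `q3`, `formatted`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) abort("empty cohort")
  n_total <- nrow(cohort)
  cont_row <- function(label, x) {
    q <- interp_quantile(x, c(0.25, 0.5, 0.75))
    tibble::tibble(
      characteristic = label, n = NA_integer_, pct = NA_real_,
      median = q[2], q1 = q[1], q3 = q[3],
      formatted = sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
    )
  }
  cat_row <- function(label, flag) {
    cnt <- sum(flag, na.rm = TRUE)
    tibble::tibble(
      characteristic = label, n = as.integer(cnt),
      pct = round_half_up(100 * cnt / n_total, 1),
      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
      formatted = fmt_count_pct(cnt, n_total)
    )
  }
  rows <- list(
    cont_row("age_years", cohort$age_years),
    cat_row("male", cohort$sex == "male"),
    cont_row("egfr", cohort$egfr),
    cont_row("map_mmHg", cohort$map_mmHg),
    cont_row("proteinuria_g_day", cohort$proteinuria_g_day),
    cat_row("mest_m1", cohort$mest_m == 1),
    cat_row("mest_e1", cohort$mest_e == 1),
    cat_row("mest_s1", cohort$mest_s == 1),
    cat_row("mest_t1", cohort$mest_t == 1),
    cat_row("mest_t2", cohort$mest_t == 2),
    cat_row("rasb_use", cohort$rasb_use),
    cat_row("is_use", cohort$is_use)
  )
  for (col in intersect(unname(novel_drug_columns), names(cohort))) {
    rows <- c(rows, list(cat_row(col, cohort[[col]])))
  }
  if ("followup_months" %in% names(cohort)) {
    rows <- c(rows, list(cont_row("followup_months", cohort$followup_months)))
  }
  if ("event" %in% names(cohort)) {
    rows <- c(rows, list(cat_row("primary_outcome", cohort$event == 1)))
  }
  dplyr::bind_rows(rows)
}

#' Read a patient cohort from CSV
#'
#' Expects one row per patient with the cohort column dictionary (see
#' [generate_cohort()]); a free-text `novel_drugs` column of `;`-separated
#' drug names is expanded into the five logical flag columns (unknown drug
#' names are an error).  Longitudinal eGFR records live in a separate
#' long-format CSV (`patient_id`, `time_months`, `egfr`).
#'
#' @param path CSV file path.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path) {
  data <- tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE)
  )
  if ("novel_drugs" %in% names(data) &&
    !all(novel_drug_columns %in% names(data))) {
    data <- dplyr::bind_cols(data, parse_novel_drugs(data$novel_drugs))
  }
  for (col in c("rasb_use", "is_use", unname(novel_drug_columns))) {
    if (col %in% names(data)) data[[col]] <- as.logical(data[[col]])
  }
  if ("proteinuria_g_day" %in% names(data) &&
    any(data$proteinuria_g_day < 0, na.rm = TRUE)) {
    abort("proteinuria must be non-negative")
  }
  if ("followup_months" %in% names(data) &&
    any(data$followup_months <= 0, na.rm = TRUE)) {
    abort("follow-up times must be positive")
  }
  data
}

#' Write a validation report to disk
#'
#' Emits `report.json` (the scalar metrics), `decile_calibration.csv`,
#' `group_table.csv`, `km_groups.csv` and, when present, `slopes.csv`.
#'
#' @param report An `iigan_validation` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "iigan_validation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    as.list(glance(report)),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  utils::write.csv(report$decile_table,
    file.path(dir, "decile_calibration.csv"),
    row.names = FALSE
  )
  group_out <- dplyr::left_join(
    report$group_table,
    dplyr::select(
      report$group_hr$hr_table, "group", "hazard_ratio",
      "conf.low", "conf.high", "p.value"
    ),
    by = "group"
  )
  utils::write.csv(group_out, file.path(dir, "group_table.csv"),
    row.names = FALSE
  )
  utils::write.csv(report$km_groups, file.path(dir, "km_groups.csv"),
    row.names = FALSE
  )
  if (!is.null(report$slopes)) {
    utils::write.csv(report$slopes, file.path(dir, "slopes.csv"),
      row.names = FALSE
    )
  }
  invisible(dir)
}
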
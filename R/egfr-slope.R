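#' Annualised eGFR slopes per risk group from a linear mixed-effects model
#'
#' Fits a linear mixed model to longitudinal eGFR records: fixed effects for
#' time, risk group, their interaction and the requested baseline adjusters,
#' with a random intercept and random slope per subject (REML).  The
#' per-group slope is the time fixed effect plus the group interaction, with
#' a 95% Wald interval from the fixed-effect covariance.  Slopes are
#' reported in mL/min/1.73 m^2 per year regardless of the input time unit.
#'
#' @param long_data Long-format eGFR records: columns `patient_id`,
#'   `time_months` (or years, see `time_unit`) and `egfr`.
#' @param cohort One row per patient, carrying the grouping column and the
#'   adjuster columns.
#' @param group Grouping column in `cohort` (default `risk_group`).
#' @param adjusters Character vector of baseline covariates to adjust for
#'   (default: age, sex, MAP, 24-h proteinuria and the MEST scores).
#' @param time,egfr,id Column names in `long_data`.
#' @param time_unit `"months"` (default) or `"years"`.
#' @return A tibble with one row per group: `group`, `n_subjects`, `slope`,
#'   `ci_lower`, `ci_upper`, plus attributes `singular_fallback` (TRUE when
#'   the random-slope covariance was singular and the model fell back to a
#'   random intercept only) and `n_dropped` (subjects with < 2 observations).
#' @export
fit_egfr_slopes <- function(long_data, cohort, group = "risk_group",
                            adjusters = c(
                              "age_years", "sex", "map_mmHg",
                              "proteinuria_g_day", "mest_m", "mest_e",
                              "mest_s", "mest_t"
                            ),
                            time = "time_months", egfr = "egfr",
                            id = "patient_id", time_unit = c("months", "years")) {
  time_unit <- match.arg(time_unit)
  long_data <- tibble::as_tibble(long_data)
  cohort <- tibble::as_tibble(cohort)
  if (!group %in% names(cohort)) {
    abort(sprintf("no `%s` column in `cohort`", group))
  }
  adjusters <- intersect(adjusters, names(cohort))
  keep_cols <- unique(c(id, group, adjusters))
  work <- dplyr::inner_join(long_data, cohort[keep_cols], by = id)
  if (anyNA(work[[group]])) abort("grouping must cover all subjects")

  obs_per_subject <- table(work[[id]])
  too_few <- names(obs_per_subject)[obs_per_subject < 2]
  if (length(too_few)) {
    warn(sprintf(
      "dropping %d subject(s) with fewer than 2 eGFR observations",
      length(too_few)
    ))
    work <- work[!work[[id]] %in% too_few, ]
  }
  obs_per_subject <- table(work[[id]])
  if (mean(obs_per_subject >= 3) < 0.5) {
    abort("need >= 3 eGFR observations for at least 50% of subjects")
  }

  df <- data.frame(
    .id = work[[id]],
    .egfr = work[[egfr]],
    .time_years = if (time_unit == "months") work[[time]] / 12 else work[[time]],
    # force an unordered factor: ordered factors would get polynomial
    # contrasts and break the per-group interaction contrasts below
    .group = {
      gf <- droplevels(factor(work[[group]]))
      factor(as.character(gf), levels = levels(gf))
    },
    work[adjusters],
    check.names = FALSE
  )
  adj_part <- if (length(adjusters)) {
    paste("+", paste(sprintf("`%s`", adjusters), collapse = " + "))
  } else {
    ""
  }
  fml <- stats::as.formula(paste(
    ".egfr ~ .time_years * .group", adj_part, "+ (1 + .time_years | .id)"
  ))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = df, REML = TRUE)
  ))
  singular_fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5)) {
    singular_fallback <- TRUE
    fml2 <- stats::as.formula(paste(
      ".egfr ~ .time_years * .group", adj_part, "+ (1 | .id)"
    ))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(fml2, data = df, REML = TRUE)
    ))
  }
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  groups <- levels(df$.group)
  n_subj <- tapply(df$.id, df$.group, function(x) length(unique(x)))
  out <- purrr::map_dfr(groups, function(g) {
    contrast <- setNames(numeric(length(beta)), names(beta))
    contrast[".time_years"] <- 1
    inter <- paste0(".time_years:.group", g)
    if (g != groups[1] && !inter %in% names(beta)) {
      abort(sprintf("internal error: missing interaction term for group %s", g))
    }
    if (inter %in% names(beta)) contrast[inter] <- 1
    slope <- sum(contrast * beta)
    se <- sqrt(drop(t(contrast) %*% vc %*% contrast))
    tibble::tibble(
      group = g,
      n_subjects = as.integer(n_subj[[g]]),
      slope = slope,
      ci_lower = slope - 1.96 * se,
      ci_upper = slope + 1.96 * se
    )
  })
  attr(out, "singular_fallback") <- singular_fallback
  attr(out, "n_dropped") <- length(too_few)
  attr(out, "fit") <- fit
  out
}
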
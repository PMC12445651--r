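#' Kaplan-Meier curve as a tibble
#'
#' Product-limit estimate with Greenwood variance and pointwise 95% bands on
#' the log(-log) scale, which keeps the bands inside \[0, 1\] (these bands are
#' the vertical whiskers of the calibration plots).  Wraps
#' [survival::survfit()].
#'
#' @param data Data frame with one row per subject.
#' @param time,event Column names of the follow-up time (months) and the
#'   event indicator (0/1 composite kidney outcome).
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, `ci_lower`, `ci_upper`.
#' @export
km_curve <- function(data, time = "followup_months", event = "event") {
  if (nrow(data) == 0) abort("empty survival sample")
  tt <- data[[time]]
  ev <- data[[event]]
  if (any(tt <= 0)) abort("follow-up times must be positive")
  fit <- survival::survfit(
    survival::Surv(tt, ev) ~ 1,
    conf.type = "log-log"
  )
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv,
    ci_lower = fit$lower,
    ci_upper = fit$upper
  )
  # degenerate band while no event has occurred (std error 0)
  out$ci_lower <- ifelse(is.na(out$ci_lower), out$survival, out$ci_lower)
  out$ci_upper <- ifelse(is.na(out$ci_upper), out$survival, out$ci_upper)
  out
}

#' Kaplan-Meier observed risk at a horizon
#'
#' @inheritParams km_curve
#' @param horizon_months Evaluation time; the estimate is carried forward
#'   from the last event time at or before the horizon.
#' @return A one-row tibble: `observed_risk` (`1 - S(t)`), `ci_lower`,
#'   `ci_upper` (on the risk scale), `n_risk`.
#' @export
km_risk_at <- function(data, horizon_months,
                       time = "followup_months", event = "event") {
  curve <- km_curve(data, time = time, event = event)
  s <- summary(
    survival::survfit(
      survival::Surv(data[[time]], data[[event]]) ~ 1,
      conf.type = "log-log"
    ),
    times = horizon_months, extend = TRUE
  )
  tibble::tibble(
    observed_risk = 1 - s$surv,
    ci_lower = 1 - ifelse(is.na(s$upper), s$surv, s$upper),
    ci_upper = 1 - ifelse(is.na(s$lower), s$surv, s$lower),
    n_risk = s$n.risk
  )
}

#' Cox proportional-hazards fit with convergence diagnostics
#'
#' Wraps [survival::coxph()] with Efron tie handling and explicit detection
#' of monotone-likelihood divergence (perfect separation), which `coxph`
#' only signals through warnings.  Returns a light-weight object with
#' [generics::tidy()] and [generics::glance()] methods.
#'
#' @param data Data frame with one row per subject.
#' @param covariates Character vector of covariate column names.
#' @inheritParams km_curve
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @return An object of class `iigan_cox`.
#' @export
fit_cox <- function(data, covariates,
                    time = "followup_months", event = "event",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (nrow(data) == 0) abort("empty survival sample")
  if (sum(data[[event]]) < 1) abort("need at least one event to fit a Cox model")
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) abort(sprintf("missing covariate column: %s", cv))
    if (is.numeric(v) && stats::var(v) == 0) {
      abort(sprintf("no variation in covariate %s", cv))
    }
    if (!is.numeric(v) && length(unique(v)) < 2) {
      abort(sprintf("no variation in covariate %s", cv))
    }
  }
  df <- data.frame(
    .time = data[[time]], .event = data[[event]],
    data[covariates], check.names = FALSE
  )
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  monotone <- FALSE
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties, model = TRUE),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|converged before|beta may be infinite", msg)) {
        monotone <<- TRUE
      }
      if (grepl("did not converge|Ran out of iterations", msg)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  # monotone likelihoods may also surface as a huge drifting coefficient
  # rather than an explicit coxph warning
  if (any(abs(stats::coef(fit)) > 10)) monotone <- TRUE
  structure(
    list(
      fit = fit,
      coefficients = stats::coef(fit),
      vcov = stats::vcov(fit),
      n = fit$n, n_event = fit$nevent,
      log_partial_likelihood = fit$loglik[length(fit$loglik)],
      ties = ties,
      converged = converged, monotone = monotone
    ),
    class = "iigan_cox"
  )
}

#' @export
print.iigan_cox <- function(x, ...) {
  cat(sprintf(
    "<iigan_cox> n = %d, events = %d, log partial likelihood = %.3f\n",
    x$n, x$n_event, x$log_partial_likelihood
  ))
  if (x$monotone) cat("  WARNING: monotone likelihood (coefficient diverges)\n")
  if (!x$converged) cat("  WARNING: did not converge\n")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Cox fit
#'
#' @param x An `iigan_cox` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`
#'   (log hazard ratio), `std.error`, `statistic`, `p.value`,
#'   `hazard_ratio`, `conf.low`, `conf.high` (95% Wald interval on the
#'   hazard-ratio scale).
#' @export
tidy.iigan_cox <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    hazard_ratio = exp(unname(est)),
    conf.low = exp(unname(est - 1.96 * se)),
    conf.high = exp(unname(est + 1.96 * se))
  )
}

#' @rdname tidy.iigan_cox
#' @export
glance.iigan_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_event = x$n_event,
    log_partial_likelihood = x$log_partial_likelihood,
    converged = x$converged, monotone = x$monotone
  )
}

#' Hazard ratios across risk groups with a trend test
#'
#' Fits a Cox model on indicator contrasts of the risk group (reference =
#' lowest group present) and, separately, a Cox model on the ordinal group
#' score (0, 1, 2, 3) whose Wald test supplies the p-value for trend.
#'
#' @param data Cohort tibble containing the grouping column.
#' @param group Column with the risk-group factor (see
#'   [assign_risk_groups()]).
#' @inheritParams km_curve
#' @return A list of class `iigan_group_hr` with elements `hr_table` (one
#'   row per group: n, events, HR with 95% CI and p-value; the reference row
#'   carries HR 1 and NA inference), `trend` (one-row tibble with the
#'   ordinal coefficient and Wald p-value), `fit` and `trend_fit`
#'   (`iigan_cox` objects).
#' @export
group_hazard_ratios <- function(data, group = "risk_group",
                                time = "followup_months", event = "event") {
  g <- data[[group]]
  if (is.null(g)) abort(sprintf("no `%s` column in `data`", group))
  g <- droplevels(factor(g, levels = levels(factor(g))))
  present <- levels(g)
  expected <- risk_group_levels()
  if (all(present %in% expected)) {
    g <- droplevels(factor(as.character(g), levels = expected))
    present <- levels(g)
    if (length(present) < 4) {
      warn(sprintf(
        "risk group(s) absent: %s; fitting on remaining groups",
        paste(setdiff(expected, present), collapse = ", ")
      ))
    }
  }
  if (length(present) < 2) abort("need at least two represented groups")
  work <- tibble::tibble(
    .time = data[[time]], .event = data[[event]],
    grp = factor(as.character(g), levels = present)
  )
  ind <- stats::model.matrix(~grp, data = work)[, -1, drop = FALSE]
  colnames(ind) <- present[-1]
  work2 <- dplyr::bind_cols(work, tibble::as_tibble(ind))
  fit <- fit_cox(work2,
    covariates = present[-1],
    time = ".time", event = ".event"
  )
  work2$ordinal_score <- as.numeric(work$grp) - 1
  trend_fit <- fit_cox(work2,
    covariates = "ordinal_score",
    time = ".time", event = ".event"
  )
  td <- tidy(fit)
  counts <- work |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      n = dplyr::n(), events = sum(.data$.event), .groups = "drop"
    )
  hr_table <- tibble::tibble(
    group = present,
    n = counts$n[match(present, as.character(counts$grp))],
    events = counts$events[match(present, as.character(counts$grp))],
    hazard_ratio = c(1, td$hazard_ratio),
    conf.low = c(NA_real_, td$conf.low),
    conf.high = c(NA_real_, td$conf.high),
    p.value = c(NA_real_, td$p.value)
  )
  structure(
    list(
      hr_table = hr_table,
      trend = dplyr::mutate(tidy(trend_fit), term = "ordinal_score"),
      fit = fit, trend_fit = trend_fit
    ),
    class = "iigan_group_hr"
  )
}

#' @export
print.iigan_group_hr <- function(x, ...) {
  cat("<iigan_group_hr>\n")
  print(x$hr_table)
  cat(sprintf("P-value for trend: %.4g\n", x$trend$p.value))
  invisible(x)
}
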
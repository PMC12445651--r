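#' Chambless-Diao time-dependent C-statistic
#'
#' Discrimination of a risk marker for a survival outcome at a fixed
#' horizon: the probability that, of a random pair in which one subject has
#' the event by the horizon and the other survives past it, the event
#' subject carries the larger marker.  Sensitivity and specificity are built
#' from Kaplan-Meier-type estimates over the marker distribution (the
#' nonparametric recursive estimator): each event time at or before the
#' horizon contributes its Kaplan-Meier mass times the empirical probability
#' that the subjects failing there out-rank the subjects still at risk
#' beyond the horizon, and the total is normalised by the Kaplan-Meier
#' cumulative incidence at the horizon.  With no censoring this reduces
#' exactly to brute-force pairwise concordance among evaluable pairs, and it
#' is invariant under strictly increasing transforms of the marker.
#'
#' @param data Data frame with one row per subject.
#' @param lp Column with the marker (linear predictor or predicted risk).
#' @param horizon_months Evaluation horizon (60 = 5-year risk).
#' @inheritParams km_curve
#' @return The estimated C-statistic in \[0, 1\].
#' @export
chambless_c <- function(data, lp = "lp", horizon_months = 60,
                        time = "followup_months", event = "event") {
  z <- data[[lp]]
  tt <- data[[time]]
  ev <- data[[event]]
  if (any(!is.finite(z))) abort("non-finite marker values")
  if (horizon_months > max(tt)) {
    abort("horizon exceeds the maximum follow-up time")
  }
  if (sum(ev[tt <= horizon_months]) < 1) {
    abort("no events before the horizon")
  }
  beyond <- sort(z[tt > horizon_months])
  m <- length(beyond)
  if (m == 0) abort("no subjects at risk beyond the horizon")
  fit <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  surv_prev <- c(1, head(fit$surv, -1))
  keep <- fit$n.event > 0 & fit$time <= horizon_months
  event_times <- fit$time[keep]
  mass <- (surv_prev - fit$surv)[keep]
  s_h <- summary(fit, times = horizon_months, extend = TRUE)$surv
  f_h <- 1 - s_h
  mean_cdf <- vapply(event_times, function(tk) {
    zi <- z[tt == tk & ev == 1]
    less <- findInterval(zi, beyond, left.open = TRUE)
    leq <- findInterval(zi, beyond)
    mean((less + 0.5 * (leq - less)) / m)
  }, numeric(1))
  sum(mass * mean_cdf) / f_h
}

#' Inverse-probability-of-censoring-weighted time-dependent AUC
#'
#' Estimates the same cumulative/dynamic AUC at the horizon as
#' [chambless_c()], but by pair enumeration with inverse
#' probability-of-censoring weights: cases (events at or before the horizon)
#' are weighted by the inverse left-continuous Kaplan-Meier estimate of the
#' censoring distribution at their failure time, controls (subjects beyond
#' the horizon) by its inverse at the horizon.  With no censoring before the
#' horizon it reduces to brute-force pairwise concordance among evaluable
#' pairs.  It serves as an independent cross-check of the Chambless-Diao
#' estimator (the primary one reported); the two can drift apart under heavy
#' censoring.
#'
#' @inheritParams chambless_c
#' @return Estimated time-dependent AUC in \[0, 1\].
#' @export
concordance_ipcw <- function(data, lp = "lp", horizon_months = 60,
                             time = "followup_months", event = "event") {
  z <- data[[lp]]
  tt <- data[[time]]
  ev <- data[[event]]
  cens_fit <- survival::survfit(survival::Surv(tt, 1 - ev) ~ 1)
  g_at <- function(t) {
    # left-continuous KM of the censoring distribution, G(t-)
    idx <- findInterval(t - 1e-9, cens_fit$time)
    c(1, cens_fit$surv)[idx + 1]
  }
  idx_case <- which(ev == 1 & tt <= horizon_months)
  idx_ctrl <- which(tt > horizon_months)
  if (length(idx_case) == 0 || length(idx_ctrl) == 0) {
    abort("no comparable pairs at the horizon")
  }
  w_ctrl_total <- length(idx_ctrl) / g_at(horizon_months)
  num <- 0
  den <- 0
  for (i in idx_case) {
    w_i <- 1 / g_at(tt[i])
    conc <- sum((z[i] > z[idx_ctrl]) + 0.5 * (z[i] == z[idx_ctrl]))
    num <- num + w_i * conc / g_at(horizon_months)
    den <- den + w_i * w_ctrl_total
  }
  num / den
}

#' Calibration slope
#'
#' The coefficient of the (externally computed) linear predictor in a Cox
#' model with the LP as the only covariate.  A slope of 1 means the spread
#' of predicted risks matches the cohort; slopes below 1 indicate the tool's
#' risk gradient is too steep for the validation cohort.
#'
#' @inheritParams chambless_c
#' @return The scalar slope (Cox coefficient).
#' @export
calibration_slope <- function(data, lp = "lp",
                              time = "followup_months", event = "event") {
  fit <- fit_cox(data, covariates = lp, time = time, event = event)
  unname(fit$coefficients[1])
}

#' Royston-Sauerbrei D statistic and R-squared(D)
#'
#' Prognostic separation: linear predictors are ranked, replaced by expected
#' standard-normal order statistics (Blom scores, constant 3/8) scaled by
#' \eqn{\kappa = \sqrt{8/\pi}}, and the Cox coefficient on that constructed
#' covariate is D.  The explained-variation measure is
#' \deqn{R^2_D = \frac{D^2/\kappa^2}{\pi^2/6 + D^2/\kappa^2}.}
#' The construction is rank-based, hence invariant under monotone-increasing
#' affine transforms of the LP.
#'
#' @inheritParams chambless_c
#' @return A one-row tibble: `d_statistic`, `r2d`.
#' @export
royston_r2d <- function(data, lp = "lp",
                        time = "followup_months", event = "event") {
  if (sum(data[[event]]) < 2) abort("need at least two events")
  n <- nrow(data)
  kappa <- sqrt(8 / pi)
  r <- rank(data[[lp]], ties.method = "average")
  blom <- stats::qnorm((r - 3 / 8) / (n + 1 / 4)) / kappa
  work <- tibble::tibble(
    .time = data[[time]], .event = data[[event]], blom_score = blom
  )
  fit <- fit_cox(work,
    covariates = "blom_score",
    time = ".time", event = ".event"
  )
  d <- unname(fit$coefficients[1])
  r2d <- (d^2 / kappa^2) / (pi^2 / 6 + d^2 / kappa^2)
  tibble::tibble(d_statistic = d, r2d = r2d)
}

#' Integrated Calibration Index (ICI)
#'
#' Mean absolute difference between each subject's predicted risk at the
#' horizon and a smoothed estimate of the observed risk at the same
#' predicted value.  The smoother regresses the outcome on
#' \eqn{\log(-\log(1 - \hat p))} through a restricted cubic spline (3 knots
#' by default, at the 10th/50th/90th percentiles) in a Cox model, from which
#' the observed risk at the horizon is read off via the Breslow baseline
#' hazard.
#'
#' @inheritParams chambless_c
#' @param risk Column with predicted risks in (0, 1); values of exactly 0 or
#'   1 are clipped with a warning.
#' @param n_knots Number of restricted-cubic-spline knots (>= 3).
#' @return The scalar ICI (>= 0).
#' @export
ici <- function(data, risk = "risk", horizon_months = 60,
                time = "followup_months", event = "event", n_knots = 3) {
  p <- clip_prob(data[[risk]])
  tt <- data[[time]]
  ev <- data[[event]]
  if (sum(ev[tt <= horizon_months]) < 1) abort("no events before the horizon")
  x <- cloglog(p)
  if (length(unique(x)) >= n_knots + 1) {
    kq <- switch(as.character(n_knots),
      "3" = c(0.10, 0.50, 0.90),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
      seq(0.05, 0.95, length.out = n_knots)
    )
    knots <- unique(interp_quantile(x, kq))
  } else {
    knots <- NULL
  }
  basis <- if (!is.null(knots) && length(knots) >= 3) {
    rcs_basis(x, knots)
  } else {
    matrix(x, ncol = 1) # too few distinct values for a spline: linear term
  }
  colnames(basis) <- paste0("cll", seq_len(ncol(basis)))
  df <- data.frame(.time = tt, .event = ev, basis)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(colnames(basis), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  bh <- survival::basehaz(fit, centered = TRUE)
  h0 <- if (any(bh$time <= horizon_months)) {
    max(bh$hazard[bh$time <= horizon_months])
  } else {
    0
  }
  lp_centered <- stats::predict(fit, type = "lp")
  observed_smoothed <- 1 - exp(-h0 * exp(lp_centered))
  mean(abs(observed_smoothed - p))
}

#' Decile calibration table
#'
#' Splits the cohort into 10 groups at the interpolated deciles of the
#' linear predictor (the same quantile convention as the risk groups) and
#' compares the mean predicted risk per group with the Kaplan-Meier observed
#' risk at the horizon.
#'
#' @inheritParams ici
#' @param lp Column with the linear predictor used for grouping.
#' @return A tibble with one row per decile: `decile`, `n`,
#'   `mean_predicted_risk`, `km_observed_risk`, `ci_lower`, `ci_upper`.
#' @export
decile_calibration <- function(data, risk = "risk", lp = "lp",
                               horizon_months = 60,
                               time = "followup_months", event = "event") {
  n <- nrow(data)
  if (n < 20) abort("need at least 20 subjects for decile calibration")
  lpv <- data[[lp]]
  qs <- interp_quantile(lpv, seq(0.1, 0.9, by = 0.1))
  grp <- findInterval(lpv, qs) + 1
  if (length(unique(grp)) < 10) abort("empty decile group")
  purrr::map_dfr(1:10, function(g) {
    sub <- data[grp == g, ]
    km <- km_risk_at(sub, horizon_months, time = time, event = event)
    tibble::tibble(
      decile = g,
      n = nrow(sub),
      mean_predicted_risk = mean(sub[[risk]]),
      km_observed_risk = km$observed_risk,
      ci_lower = km$ci_lower,
      ci_upper = km$ci_upper
    )
  })
}

#' Predicted versus observed risk by risk group
#'
#' @inheritParams decile_calibration
#' @param group Column with the risk-group factor.
#' @return A tibble with one row per group: `group`, `n`, `events`,
#'   `mean_predicted_risk`, `km_observed_risk`, `ci_lower`, `ci_upper`.
#' @export
group_risk_comparison <- function(data, risk = "risk", group = "risk_group",
                                  horizon_months = 60,
                                  time = "followup_months", event = "event") {
  g <- data[[group]]
  if (is.null(g) || anyNA(g)) abort("grouping must cover the sample")
  purrr::map_dfr(levels(factor(g)), function(lev) {
    sub <- data[g == lev, ]
    km <- km_risk_at(sub, horizon_months, time = time, event = event)
    tibble::tibble(
      group = lev,
      n = nrow(sub),
      events = sum(sub[[event]]),
      mean_predicted_risk = mean(sub[[risk]]),
      km_observed_risk = km$observed_risk,
      ci_lower = km$ci_lower,
      ci_upper = km$ci_upper
    )
  })
}

#' Full validation battery for one set of predictions
#'
#' Computes the complete external-validation report from a cohort that
#' already carries linear predictors and predicted risks: Chambless-Diao
#' C-statistic, calibration slope, ICI, Royston-Sauerbrei D and R-squared(D),
#' the decile calibration table, the risk-group comparison table, and the
#' group hazard ratios with trend test.
#'
#' @inheritParams decile_calibration
#' @param scenario_id Free-text label stored in the report.
#' @return An object of class `iigan_validation` with fields
#'   `scenario_id`, `n`, `n_event`, `horizon_months`, `c_statistic`,
#'   `calibration_slope`, `ici`, `d_statistic`, `r2d`, `decile_table`,
#'   `group_table`, `group_hr`, and `km_groups` (per-group KM curves).
#' @export
validate_predictions <- function(data, scenario_id = "scenario",
                                 risk = "risk", lp = "lp",
                                 horizon_months = 60,
                                 time = "followup_months", event = "event") {
  if (!"risk_group" %in% names(data)) {
    data <- assign_risk_groups(data, lp = lp)
  }
  rd <- royston_r2d(data, lp = lp, time = time, event = event)
  km_groups <- data |>
    dplyr::group_by(risk_group = .data$risk_group) |>
    dplyr::group_modify(~ km_curve(.x, time = time, event = event)) |>
    dplyr::ungroup()
  structure(
    list(
      scenario_id = scenario_id,
      n = nrow(data),
      n_event = sum(data[[event]]),
      horizon_months = horizon_months,
      c_statistic = chambless_c(data,
        lp = lp, horizon_months = horizon_months,
        time = time, event = event
      ),
      calibration_slope = calibration_slope(data,
        lp = lp, time = time, event = event
      ),
      ici = ici(data,
        risk = risk, horizon_months = horizon_months,
        time = time, event = event
      ),
      d_statistic = rd$d_statistic,
      r2d = rd$r2d,
      decile_table = decile_calibration(data,
        risk = risk, lp = lp, horizon_months = horizon_months,
        time = time, event = event
      ),
      group_table = group_risk_comparison(data,
        risk = risk, horizon_months = horizon_months,
        time = time, event = event
      ),
      group_hr = group_hazard_ratios(data, time = time, event = event),
      km_groups = km_groups
    ),
    class = "iigan_validation"
  )
}

#' @export
print.iigan_validation <- function(x, ...) {
  cat(sprintf(
    "<iigan_validation> %s: n = %d, events = %d, horizon = %g months\n",
    x$scenario_id, x$n, x$n_event, x$horizon_months
  ))
  print(glance(x))
  invisible(x)
}

#' Tidy and glance methods for validation reports
#'
#' `glance()` gives the one-row metric summary (the shape of a journal
#' performance table); `tidy()` stacks the per-decile and per-group
#' calibration tables in long form.
#'
#' @param x An `iigan_validation` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.iigan_validation <- function(x, ...) {
  tibble::tibble(
    scenario_id = x$scenario_id,
    n = x$n,
    n_event = x$n_event,
    horizon_months = x$horizon_months,
    c_statistic = x$c_statistic,
    calibration_slope = x$calibration_slope,
    ici = x$ici,
    d_statistic = x$d_statistic,
    r2d = x$r2d,
    trend_p = x$group_hr$trend$p.value
  )
}

#' @rdname glance.iigan_validation
#' @export
tidy.iigan_validation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$decile_table,
      table = "decile_calibration",
      group = as.character(.data$decile), events = NA_integer_
    ),
    dplyr::mutate(x$group_table, table = "risk_groups", decile = NA_integer_)
  ) |>
    dplyr::select(
      "table", "group", "n", "events",
      "mean_predicted_risk", "km_observed_risk", "ci_lower", "ci_upper"
    )
}
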
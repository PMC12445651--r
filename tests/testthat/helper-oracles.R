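# Independent oracles used by the dual-route checks.  These deliberately
# avoid the code paths they verify: the Cox oracle is a direct evaluation of
# the partial likelihood maximised by numerical search, the concordance
# oracle enumerates pairs, and the KM oracle is the hand product-limit.

# Efron-tie Cox log partial likelihood for a single covariate.
cox_partial_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    sum_r <- sum(exp(eta[r_idx]))
    sum_d <- sum(exp(eta[d_idx]))
    ll <- ll + sum(eta[d_idx])
    for (j in seq_len(d) - 1) {
      ll <- ll - log(sum_r - (j / d) * sum_d)
    }
  }
  ll
}

# Maximise the partial likelihood by 1-d numerical search.
grid_search_cox <- function(time, event, x, lower = -6, upper = 6) {
  stats::optimize(
    function(b) cox_partial_loglik(b, time, event, x),
    c(lower, upper),
    maximum = TRUE, tol = 1e-9
  )$maximum
}

# Brute-force pairwise concordance among subjects evaluable at the horizon:
# cases have an observed event at or before the horizon, controls survive
# past it.
brute_force_concordance <- function(lp, time, event, horizon) {
  case <- which(event == 1 & time <= horizon)
  ctrl <- which(time > horizon)
  num <- 0
  for (i in case) {
    num <- num + sum(lp[i] > lp[ctrl]) + 0.5 * sum(lp[i] == lp[ctrl])
  }
  num / (length(case) * length(ctrl))
}

# Rank-based AUC P(z_case > z_ctrl): used by the large-sample Monte Carlo
# oracle for the C-statistic implied by the LP distribution.
auc_rank <- function(z_case, z_ctrl) {
  n1 <- length(z_case)
  r <- rank(c(z_case, z_ctrl))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(z_ctrl))
}

# Exponential survival data with hazard exp(beta * x), optional uniform
# censoring window in months.
sim_cox_sample <- function(n, beta, base_rate = 0.01, x = stats::rnorm(n),
                           censor = NULL) {
  t_event <- stats::rexp(n, rate = base_rate * exp(beta * x))
  if (is.null(censor)) {
    tibble::tibble(
      followup_months = t_event, event = 1L, x = x, lp = beta * x
    )
  } else {
    cc <- stats::runif(n, censor[1], censor[2])
    tibble::tibble(
      followup_months = pmin(t_event, cc),
      event = as.integer(t_event <= cc),
      x = x, lp = beta * x
    )
  }
}

# Small ad-hoc coefficient sets for unit tests.
toy_set <- function(terms, baseline = data.frame(
                      time_months = c(36, 60, 80),
                      s0 = c(0.95, 0.9, 0.85)
                    ),
                    variant = "without_race", race_piecewise = NULL) {
  coefficient_set(
    model_id = "at_biopsy", variant = variant, terms = terms,
    race_piecewise = race_piecewise,
    baseline_survival = baseline, label = "ad-hoc test set"
  )
}
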
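test_that("the generator is deterministic given a seed", {
  c1 <- generate_cohort(cohort_config(n = 200, seed = 123))
  c2 <- generate_cohort(cohort_config(n = 200, seed = 123))
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(n = 200, seed = 124))
  expect_false(identical(c1$egfr, c3$egfr))
})

test_that("default marginals land on the emulated cohort targets", {
  cohort <- generate_cohort(cohort_config(n = 677, seed = 1))
  expect_lt(abs(median(cohort$age_years) - 22) / 22, 0.10)
  expect_lt(abs(median(cohort$egfr) - 76) / 76, 0.10)
  expect_lt(abs(median(cohort$map_mmHg) - 99) / 99, 0.10)
  expect_lt(abs(median(cohort$proteinuria_g_day) - 1.4) / 1.4, 0.10)
  expect_lt(abs(mean(cohort$mest_m) - 0.508), 0.05)
  # every subject is on at least one novel drug (cohort definition)
  any_drug <- cohort$novel_era | cohort$novel_sglt2i | cohort$novel_nefecon |
    cohort$novel_hcq | cohort$novel_telitacicept
  expect_true(all(any_drug))
  # ERA/SGLT2i-only regimens sit near their 12.1% design mass
  expect_lt(abs(mean(era_sglt2i_only(cohort)) - 0.121), 0.04)
  expect_true(all(cohort$followup_months > 0))
  expect_true(all(cohort$egfr > 15))
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(n = 0), "positive")
  expect_error(cohort_config(hazard_multiplier = -1), "positive")
  expect_error(
    cohort_config(event_process = list(weibull_shape = -2)),
    "shape"
  )
})

test_that("the event fraction is monotone in the hazard multiplier", {
  fracs <- vapply(c(0.5, 1, 2), function(theta) {
    mean(generate_cohort(
      cohort_config(n = 1500, seed = 99, hazard_multiplier = theta)
    )$event)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("noiseless trajectories carry the subject slope exactly", {
  cfg <- cohort_config(
    n = 30, seed = 7,
    trajectory = list(slope_sd = 0, noise_sd = 0,
      slope_mean_by_quartile = rep(-3, 4))
  )
  cohort <- generate_cohort(cfg)
  traj <- generate_trajectories(cohort, cfg)
  ols <- traj |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      slope = stats::coef(stats::lm(egfr ~ I(time_months / 12)))[2]
    )
  expect_equal(unname(ols$slope), rep(-3, 30), tolerance = 1e-8)
  expect_error(
    generate_trajectories(cohort, cohort_config(
      n = 30, trajectory = list(visit_interval = 0)
    )),
    "visit"
  )
})

test_that("the random-slope standard deviation is recoverable from trajectories", {
  cfg <- cohort_config(
    n = 500, seed = 17,
    censoring = list(admin_min = 60, admin_max = 120),
    trajectory = list(slope_sd = 1, noise_sd = 3)
  )
  cohort <- generate_cohort(cfg)
  traj <- generate_trajectories(cohort, cfg)
  fit <- suppressWarnings(lme4::lmer(
    egfr ~ I(time_months / 12) + (I(time_months / 12) | patient_id),
    data = traj, REML = TRUE
  ))
  sd_hat <- attr(lme4::VarCorr(fit)$patient_id, "stddev")[2]
  expect_lt(abs(sd_hat - 1) / 1, 0.25)
})

test_that("outcome reconciliation places events at the trajectory crossing time", {
  row <- tibble::tibble(
    patient_id = "X", egfr = 80, slope_true = -10, censor_months = 100,
    followup_months = 100, event = 0L
  )
  rec <- reconcile_outcomes(row)
  expect_equal(rec$followup_months, 48) # 80 -> 40 at -10/year
  expect_equal(rec$event, 1L)
  # censored before the crossing: no event
  row2 <- dplyr::mutate(row, censor_months = 30)
  rec2 <- reconcile_outcomes(row2)
  expect_equal(rec2$event, 0L)
  expect_equal(rec2$followup_months, 30)
  # non-declining eGFR never crosses
  row3 <- dplyr::mutate(row, slope_true = 1)
  expect_equal(reconcile_outcomes(row3)$event, 0L)
})

test_that("pipeline C-statistic matches a large-sample Monte-Carlo oracle", {
  cohort <- generate_cohort(cohort_config(n = 5000, seed = 29))
  c_hat <- chambless_c(
    dplyr::rename(cohort, lp = lp_true),
    horizon_months = 60
  )
  # oracle: the concordance implied by the LP distribution and the event
  # model, from a fresh large uncensored draw and rank-based AUC
  withr::local_seed(30)
  cfg_big <- cohort_config(n = 100000)
  cfg_big$coeffs <- iigan_coefficient_set(
    "synthetic_reference_at_biopsy", "with_race"
  )
  cov <- iganpt:::sample_covariates(cfg_big$n, cfg_big)
  lp <- compute_linear_predictor(cov, cfg_big$coeffs)$lp
  tev <- iganpt:::sample_event_times(lp, cov$race, cfg_big)
  c_oracle <- auc_rank(lp[tev <= 60], lp[tev > 60])
  expect_lt(abs(c_hat - c_oracle), 0.03)
})
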
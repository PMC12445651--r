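test_that("Chambless C hits the degenerate anchors", {
  withr::local_seed(2)
  # no discrimination: constant marker
  d <- tibble::tibble(
    followup_months = stats::rexp(60, 0.02) + 0.1, event = 1L, lp = 1
  )
  expect_equal(chambless_c(d, horizon_months = 30), 0.5)
  # perfect ranking: event time strictly decreasing in the marker
  lp <- stats::rnorm(50)
  d2 <- tibble::tibble(followup_months = 100 - 10 * lp, event = 1L, lp = lp)
  expect_equal(chambless_c(d2, horizon_months = 100 - 10 * median(lp)), 1)
  expect_error(
    chambless_c(dplyr::mutate(d2, event = 0L), horizon_months = 60),
    "no events"
  )
})

test_that("Chambless C equals brute-force pairwise concordance when uncensored", {
  withr::local_seed(19)
  for (rep in 1:8) {
    n <- sample(8:12, 1)
    lp <- stats::rnorm(n)
    d <- tibble::tibble(
      followup_months = stats::rexp(n, 0.05 * exp(lp)), event = 1L, lp = lp
    )
    h <- stats::median(d$followup_months)
    if (sum(d$event & d$followup_months <= h) == 0) next
    if (sum(d$followup_months > h) == 0) next
    expect_equal(
      chambless_c(d, horizon_months = h),
      brute_force_concordance(d$lp, d$followup_months, d$event, h),
      tolerance = 1e-10
    )
  }
})

test_that("Chambless C is invariant under increasing marker transforms and tracks IPCW", {
  withr::local_seed(23)
  d <- sim_cox_sample(400, beta = 0.8, censor = c(20, 300))
  h <- 60
  c1 <- chambless_c(d, lp = "lp", horizon_months = h)
  d$lp2 <- exp(2 * d$lp + 1)
  expect_equal(chambless_c(d, lp = "lp2", horizon_months = h), c1)
  # independent IPCW estimator agrees under light censoring
  expect_lt(abs(c1 - concordance_ipcw(d, lp = "lp", horizon_months = h)), 0.05)
})

test_that("calibration slope recovers 1 under self-generation, halves on doubled LPs", {
  withr::local_seed(31)
  d <- sim_cox_sample(2000, beta = 1)
  slope <- calibration_slope(d, lp = "lp")
  expect_lt(abs(slope - 1), 0.1)
  d$lp_double <- 2 * d$lp
  expect_equal(
    calibration_slope(d, lp = "lp_double"), slope / 2,
    tolerance = 1e-6
  )
  d$lp_null <- stats::rnorm(nrow(d))
  expect_lt(abs(calibration_slope(d, lp = "lp_null")), 0.1)
  expect_error(
    calibration_slope(dplyr::mutate(d, lp_const = 1), lp = "lp_const"),
    "no variation"
  )
})

test_that("Royston D/R2D: null near zero, exact rank-invariance", {
  withr::local_seed(37)
  d <- tibble::tibble(
    followup_months = stats::rexp(800, 0.02), event = 1L,
    lp = stats::rnorm(800)
  )
  rd <- royston_r2d(d)
  expect_lt(abs(rd$d_statistic), 0.15)
  expect_lt(rd$r2d, 0.02)
  # affine transforms with positive scale leave ranks, hence D, unchanged
  d$lp_affine <- 3 * d$lp + 10
  expect_equal(royston_r2d(d, lp = "lp_affine"), rd, tolerance = 1e-10)
  expect_error(
    royston_r2d(dplyr::mutate(d, event = c(1L, rep(0L, 799)))),
    "two events"
  )
})

test_that("ICI recovers a constant miscalibration offset and flags clipping", {
  withr::local_seed(41)
  n <- 3000
  lp <- stats::rnorm(n, sd = 0.8)
  h0_60 <- 0.15
  true_risk <- 1 - exp(-h0_60 * exp(lp))
  t_event <- stats::rexp(n, h0_60 / 60 * exp(lp))
  d <- tibble::tibble(
    followup_months = t_event, event = 1L,
    risk_true = true_risk,
    risk_offset = pmin(true_risk + 0.10, 1 - 1e-6)
  )
  expect_lt(ici(d, risk = "risk_true", horizon_months = 60), 0.03)
  offset_ici <- ici(d, risk = "risk_offset", horizon_months = 60)
  expect_lt(abs(offset_ici - 0.10), 0.02)
  # risks of exactly 0/1 are clipped with a warning
  d$risk_bad <- d$risk_true
  d$risk_bad[1:3] <- c(0, 1, 0.5)
  expect_warning(ici(d, risk = "risk_bad", horizon_months = 60), "clipped")
})

test_that("decile calibration uses the interpolated-quantile convention", {
  withr::local_seed(43)
  d <- tibble::tibble(
    followup_months = stats::rexp(100, 0.01) + 1, event = 1L,
    lp = stats::rnorm(100)
  )
  d$risk <- stats::plogis(d$lp)
  dc <- decile_calibration(d, horizon_months = stats::median(d$followup_months))
  expect_equal(dc$n, rep(10L, 10))
  expect_error(
    decile_calibration(dplyr::mutate(d, lp = 1)),
    "decile"
  )
  expect_error(decile_calibration(d[1:10, ]), "at least 20")
})

test_that("halving the generating hazard makes every decile overpredicted", {
  cfg <- cohort_config(n = 4000, seed = 47, hazard_multiplier = 0.5)
  cohort <- generate_cohort(cfg)
  cs <- iigan_coefficient_set("synthetic_reference_at_biopsy", "with_race")
  preds <- add_risk_predictions(cohort, cs)
  dc <- decile_calibration(preds)
  expect_true(all(dc$mean_predicted_risk > dc$km_observed_risk))
})

test_that("group risk comparison reports the canonical group sizes", {
  withr::local_seed(53)
  d <- tibble::tibble(
    followup_months = stats::rexp(677, 0.015) + 0.5, event = 1L,
    lp = stats::rnorm(677)
  )
  d$risk <- stats::plogis(d$lp - 2)
  d <- assign_risk_groups(d)
  gt <- group_risk_comparison(d, horizon_months = 30)
  expect_equal(gt$n[match(risk_group_levels(), gt$group)], c(109, 230, 229, 109))
  expect_equal(sum(gt$events), sum(d$event[d$followup_months <= Inf]))
})

test_that("validate_predictions assembles a deterministic full report", {
  cohort <- generate_cohort(cohort_config(n = 600, seed = 59))
  cs <- iigan_coefficient_set("synthetic_reference_at_biopsy", "with_race")
  preds <- add_risk_predictions(cohort, cs) |> assign_risk_groups()
  rep1 <- validate_predictions(preds, scenario_id = "unit")
  rep2 <- validate_predictions(preds, scenario_id = "unit")
  expect_equal(glance(rep1), glance(rep2))
  g <- glance(rep1)
  expect_true(g$c_statistic > 0.5 && g$c_statistic < 1)
  expect_true(g$r2d >= 0 && g$r2d < 1)
  expect_gte(g$ici, 0)
  expect_equal(nrow(rep1$decile_table), 10)
  expect_equal(nrow(rep1$group_table), 4)
  td <- tidy(rep1)
  expect_equal(nrow(td), 14)
})
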
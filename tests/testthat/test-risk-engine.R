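test_that("linear predictor reproduces hand-computed dot products", {
  # every transformed covariate at its centering value gives LP = 0
  cs <- toy_set(data.frame(
    covariate = c("proteinuria_g_day", "egfr"),
    transform = c("log", "identity"), level = NA,
    center = c(log(1.4), 76), coefficient = c(0.5, -0.02)
  ))
  at_center <- tibble::tibble(proteinuria_g_day = 1.4, egfr = 76)
  expect_equal(compute_linear_predictor(at_center, cs)$lp, 0)

  # single log term: coeff 0.5, center 0, proteinuria = e
  cs1 <- toy_set(data.frame(
    covariate = "proteinuria_g_day", transform = "log", level = NA,
    center = 0, coefficient = 0.5
  ))
  expect_equal(
    compute_linear_predictor(
      tibble::tibble(proteinuria_g_day = exp(1)), cs1
    )$lp,
    0.5
  )

  # two identity terms: 0.3 * (3 - 1) - 0.2 * (2 - 0) = 0.2
  cs2 <- toy_set(data.frame(
    covariate = c("x1", "x2"), transform = "identity", level = NA,
    center = c(1, 0), coefficient = c(0.3, -0.2)
  ))
  expect_equal(
    compute_linear_predictor(tibble::tibble(x1 = 3, x2 = 2), cs2)$lp,
    0.2
  )
})

test_that("linear predictor is additive over terms", {
  withr::local_seed(42)
  cohort <- generate_cohort(cohort_config(n = 40, seed = 7))
  cs <- iigan_coefficient_set("synthetic_reference_at_biopsy", "with_race")
  full <- compute_linear_predictor(cohort, cs)$lp
  single <- purrr::map(seq_len(nrow(cs$terms)), function(i) {
    csi <- cs
    csi$terms <- cs$terms[i, ]
    compute_linear_predictor(cohort, csi)$lp
  })
  expect_equal(Reduce(`+`, single), full, tolerance = 1e-12)
})

test_that("missing covariates and unknown transforms are explicit errors", {
  cs <- toy_set(data.frame(
    covariate = "egfr", transform = "identity", level = NA,
    center = 76, coefficient = -0.02
  ))
  expect_error(
    compute_linear_predictor(tibble::tibble(age_years = 30), cs),
    "egfr"
  )
  expect_error(
    compute_linear_predictor(tibble::tibble(egfr = NA_real_), cs),
    "egfr"
  )
})

test_that("risk matches the closed-form survival power and is monotone", {
  cs <- toy_set(
    data.frame(
      covariate = "x", transform = "identity", level = NA,
      center = 0, coefficient = 1
    ),
    baseline = data.frame(time_months = c(60, 80), s0 = c(0.9, 0.85))
  )
  # lp = 0 -> risk = 1 - S0(60) = 0.1; lp = ln 2 -> 1 - 0.9^2
  d <- tibble::tibble(x = c(0, log(2)))
  r <- predict_risk(d, cs, horizon_months = 60)
  expect_equal(r$risk, c(0.1, 1 - 0.9^2), tolerance = 1e-12)

  # strictly increasing in lp, non-decreasing in horizon
  lps <- tibble::tibble(x = seq(-2, 2, length.out = 21))
  r60 <- predict_risk(lps, cs, 60)$risk
  r80 <- predict_risk(lps, cs, 80)$risk
  expect_true(all(diff(r60) > 0))
  expect_true(all(r80 >= r60))
  expect_error(predict_risk(lps, cs, 120), "span")
})

test_that("piecewise race hazard matches the stated formula and collapses when betas agree", {
  pw <- list(
    race = "chinese", cutpoint_months = 36,
    beta_early = 0.3, beta_late = -0.2
  )
  # H0(36) = 0.1, H0(60) = 0.2
  bs <- data.frame(time_months = c(36, 60), s0 = exp(-c(0.1, 0.2)))
  cs <- toy_set(
    data.frame(
      covariate = "x", transform = "identity", level = NA,
      center = 0, coefficient = 1
    ),
    baseline = bs, variant = "with_race", race_piecewise = pw
  )
  d <- tibble::tibble(x = 0, race = "chinese")
  expect_equal(
    predict_risk(d, cs, 60)$risk,
    1 - exp(-(0.1 * exp(0.3) + 0.1 * exp(-0.2))),
    tolerance = 1e-12
  )
  # a patient of another race uses the plain formula
  expect_equal(
    predict_risk(tibble::tibble(x = 0, race = "white"), cs, 60)$risk,
    1 - exp(-0.2),
    tolerance = 1e-12
  )
  # beta_early = beta_late reduces to the plain formula with that offset
  pw_eq <- list(
    race = "chinese", cutpoint_months = 36,
    beta_early = 0.25, beta_late = 0.25
  )
  cs_eq <- toy_set(
    data.frame(
      covariate = "x", transform = "identity", level = NA,
      center = 0, coefficient = 1
    ),
    baseline = bs, variant = "with_race", race_piecewise = pw_eq
  )
  lps <- seq(-1, 1, length.out = 7)
  got <- predict_risk(tibble::tibble(x = lps, race = "chinese"), cs_eq, 60)$risk
  expect_equal(got, 1 - exp(-0.2 * exp(lps + 0.25)), tolerance = 1e-12)
})

test_that("novel drugs remap onto RASB/immunosuppressant flags and remapping is idempotent", {
  base <- tibble::tibble(
    rasb_use = FALSE, is_use = FALSE,
    novel_era = FALSE, novel_sglt2i = FALSE, novel_nefecon = FALSE,
    novel_hcq = FALSE, novel_telitacicept = FALSE
  )
  sglt <- dplyr::mutate(base, novel_sglt2i = TRUE)
  out <- remap_novel_drugs(sglt)
  expect_true(out$rasb_use)
  expect_false(out$is_use)

  teli <- dplyr::mutate(base, novel_telitacicept = TRUE)
  out2 <- remap_novel_drugs(teli)
  expect_true(out2$is_use)
  expect_false(out2$rasb_use)

  # empty drug set leaves the record unchanged
  expect_equal(remap_novel_drugs(base), base)

  # idempotence on a generated cohort
  cohort <- generate_cohort(cohort_config(n = 60, seed = 3))
  once <- remap_novel_drugs(cohort)
  expect_equal(remap_novel_drugs(once), once)

  # free-text drug lists are parsed, unknown names rejected
  txt <- dplyr::mutate(base[, 1:2], novel_drugs = "SGLT2i;HCQ")
  parsed <- remap_novel_drugs(txt)
  expect_true(parsed$rasb_use & parsed$is_use)
  expect_error(
    remap_novel_drugs(dplyr::mutate(base[, 1:2], novel_drugs = "rituximab")),
    "unknown novel drug"
  )
})

test_that("percentile grouping reproduces the canonical counts on tie-free LPs", {
  withr::local_seed(11)
  for (case in list(
    list(n = 677, counts = c(109, 230, 229, 109)),
    list(n = 566, counts = c(91, 192, 192, 91)),
    list(n = 100, counts = c(16, 34, 34, 16))
  )) {
    lp <- stats::runif(case$n)
    grp <- assign_risk_groups(lp)
    expect_equal(as.integer(table(grp))[1:4], case$counts)
  }
})

test_that("grouping flags degenerate input and boundary ties", {
  expect_error(assign_risk_groups(c(1, 2, 3)), "at least 4")
  expect_error(assign_risk_groups(rep(1, 10)), "identical")
  # a duplicated value landing on the median boundary triggers a warning
  lp <- c(1, 2, 3, 4, 4, 4, 5, 6, 7, 8, 9)
  expect_warning(assign_risk_groups(lp), "tie")
  # data-frame interface appends the factor
  d <- assign_risk_groups(tibble::tibble(lp = stats::runif(50)))
  expect_s3_class(d$risk_group, "factor")
  expect_equal(sum(table(d$risk_group)), 50)
})

test_that("CKD-EPI at the sex-specific knots matches the published constants", {
  # female, age 40, Scr 0.7 mg/dL: both min/max terms are 1
  expect_equal(
    ckd_epi_egfr(0.7 * 88.4, 40, "female"), 144 * 0.993^40,
    tolerance = 1e-10
  )
  expect_equal(
    ckd_epi_egfr(0.9 * 88.4, 50, "male"), 141 * 0.993^50,
    tolerance = 1e-10
  )
  expect_lt(abs(ckd_epi_egfr(0.7 * 88.4, 40, "female") - 108.7), 0.1)
  expect_lt(abs(ckd_epi_egfr(0.9 * 88.4, 50, "male") - 99.2), 0.1)
  # doubling creatinine strictly decreases eGFR
  scr <- c(50, 80, 120, 200)
  expect_true(all(
    ckd_epi_egfr(2 * scr, 40, "male") < ckd_epi_egfr(scr, 40, "male")
  ))
  expect_error(ckd_epi_egfr(-1, 40, "male"), "positive")
})
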
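#' Evaluate the IIgAN-PT linear predictor on a cohort
#'
#' Computes the Cox linear predictor
#' \eqn{LP = \sum_j \beta_j \,(x_j - c_j)} over the terms of a coefficient
#' set, where each \eqn{x_j} is the (possibly transformed) covariate value and
#' \eqn{c_j} its centering constant.  Time-constant race terms contribute
#' here; the piecewise 36-month race effect is applied in [predict_risk()]
#' because it modifies the hazard, not the linear predictor.
#'
#' @param data A cohort data frame, one row per patient, with columns named
#'   after the covariates of `coeffs` (see [generate_cohort()] for the column
#'   dictionary).
#' @param coeffs An [`iigan_coefficient_set`][coefficient_set].
#' @return The input as a tibble with an `lp` column appended.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 1))
#' compute_linear_predictor(cohort, iigan_coefficient_set("toy"))
compute_linear_predictor <- function(data, coeffs) {
  stopifnot(inherits(coeffs, "iigan_coefficient_set"))
  data <- tibble::as_tibble(data)
  terms <- coeffs$terms
  lp <- numeric(nrow(data))
  for (i in seq_len(nrow(terms))) {
    tm <- terms[i, ]
    if (!tm$covariate %in% names(data)) {
      abort(sprintf("missing required covariate: %s", tm$covariate))
    }
    v <- data[[tm$covariate]]
    if (anyNA(v)) {
      abort(sprintf("missing values in required covariate: %s", tm$covariate))
    }
    x <- switch(tm$transform,
      identity = as.numeric(v),
      log = {
        if (any(v <= 0)) {
          abort(sprintf("log transform of non-positive %s", tm$covariate))
        }
        log(as.numeric(v))
      },
      indicator = as.numeric(v == tm$level),
      abort(sprintf("unknown transform_spec: %s", tm$transform))
    )
    lp <- lp + tm$coefficient * (x - tm$center)
  }
  dplyr::mutate(data, lp = lp)
}

# Baseline cumulative hazard H0(t) = -log S0(t), linearly interpolated on the
# coefficient set's time grid with H0(0) = 0.  Errors outside the span.
baseline_cumhaz <- function(coeffs, t) {
  bs <- coeffs$baseline_survival
  tmax <- max(bs$time_months)
  if (any(t < 0 | t > tmax)) {
    abort(sprintf(
      "horizon outside the span of the baseline survival (0..%g months)", tmax
    ))
  }
  grid_t <- c(0, bs$time_months)
  grid_h <- c(0, -log(bs$s0))
  stats::approx(grid_t, grid_h, xout = t, ties = "ordered")$y
}

#' Absolute outcome risk at a horizon
#'
#' Converts linear predictors into the cumulative risk of the composite
#' kidney outcome at `horizon_months`.  Without a piecewise race term the
#' risk is \eqn{1 - S_0(t)^{\exp(LP)}}.  For patients of the race carrying
#' the piecewise effect (the proportional-hazards violation handled by the
#' published tool at 36 months),
#' \deqn{risk = 1 - \exp\{-[H_0(\min(t, 36))e^{LP+\beta_{early}} +
#'   \max(0, H_0(t) - H_0(36))e^{LP+\beta_{late}}]\}}
#' with \eqn{H_0 = -\log S_0}.
#'
#' @inheritParams compute_linear_predictor
#' @param horizon_months Prediction horizon in months (60 = the 5-year risk
#'   used throughout the validation).  Must lie within the span of the
#'   baseline survival.
#' @param lp Column holding the linear predictor (default `lp`; computed
#'   first with [compute_linear_predictor()] if absent).
#' @return The input tibble with `risk` and `horizon_months` columns.
#' @export
predict_risk <- function(data, coeffs, horizon_months = 60, lp = "lp") {
  stopifnot(inherits(coeffs, "iigan_coefficient_set"))
  stopifnot(length(horizon_months) == 1, is.finite(horizon_months))
  if (!lp %in% names(data)) {
    data <- compute_linear_predictor(data, coeffs)
    lp <- "lp"
  }
  data <- tibble::as_tibble(data)
  lpv <- data[[lp]]
  if (any(!is.finite(lpv))) abort("non-finite linear predictor")
  h_t <- baseline_cumhaz(coeffs, horizon_months)
  pw <- coeffs$race_piecewise
  if (is.null(pw) || !"race" %in% names(data)) {
    risk <- 1 - exp(-h_t * exp(lpv))
  } else {
    cut <- pw$cutpoint_months
    h_early <- baseline_cumhaz(coeffs, min(horizon_months, cut))
    h_late <- max(0, h_t - baseline_cumhaz(coeffs, min(cut, max(
      coeffs$baseline_survival$time_months
    ))))
    active <- data$race == pw$race
    cumhaz <- ifelse(
      active,
      h_early * exp(lpv + pw$beta_early) + h_late * exp(lpv + pw$beta_late),
      h_t * exp(lpv)
    )
    risk <- 1 - exp(-cumhaz)
  }
  dplyr::mutate(data, risk = risk, horizon_months = horizon_months)
}

#' Compute linear predictors and risks in one step
#'
#' @inheritParams predict_risk
#' @return The cohort tibble with `lp`, `risk` and `horizon_months` columns.
#' @export
add_risk_predictions <- function(data, coeffs, horizon_months = 60) {
  data |>
    compute_linear_predictor(coeffs) |>
    predict_risk(coeffs, horizon_months = horizon_months)
}

# Canonical novel-therapy flag columns and the names accepted in free-text
# `novel_drugs` strings.
novel_drug_columns <- c(
  ERA = "novel_era", SGLT2i = "novel_sglt2i", Nefecon = "novel_nefecon",
  HCQ = "novel_hcq", telitacicept = "novel_telitacicept"
)

# Parse "SGLT2i;HCQ"-style strings into the five logical flag columns.
parse_novel_drugs <- function(x) {
  tokens <- strsplit(ifelse(is.na(x) | x == "", "", x), "[;,+ ]+")
  known <- names(novel_drug_columns)
  alias <- c(known, "hydroxychloroquine")
  bad <- setdiff(unique(unlist(tokens)), c(alias, toupper(alias), tolower(alias)))
  if (length(bad)) {
    abort(sprintf("unknown novel drug name(s): %s", paste(bad, collapse = ", ")))
  }
  canon <- function(tok) {
    tok <- tolower(tok)
    tok[tok == "hydroxychloroquine"] <- "hcq"
    tok
  }
  out <- lapply(known, function(drug) {
    vapply(tokens, function(tk) tolower(drug) %in% canon(tk), logical(1))
  })
  names(out) <- unname(novel_drug_columns)
  tibble::as_tibble(out)
}

#' Remap novel therapies onto the tool's historical drug variables
#'
#' The published tool predates the novel IgAN therapies, so its only drug
#' inputs are RAS-blocker and immunosuppressant use.  This remapping feeds
#' the novel agents into those variables by mechanism: ERAs and SGLT2
#' inhibitors count as RAS blockers (supportive, haemodynamic), while
#' Nefecon, hydroxychloroquine and telitacicept count as immunosuppressants
#' (immunomodulatory).  The novel-drug flags themselves are left untouched,
#' and the operation is idempotent.
#'
#' @param data A cohort tibble with `rasb_use`, `is_use` and either the five
#'   logical flag columns `novel_era`, `novel_sglt2i`, `novel_nefecon`,
#'   `novel_hcq`, `novel_telitacicept` or a character column `novel_drugs`
#'   of `;`-separated drug names (unknown names are an error).
#' @return A remapped copy of `data`.
#' @export
remap_novel_drugs <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(novel_drug_columns %in% names(data))) {
    if (!"novel_drugs" %in% names(data)) {
      abort("need novel-drug flag columns or a `novel_drugs` column")
    }
    data <- dplyr::bind_cols(data, parse_novel_drugs(data$novel_drugs))
  }
  dplyr::mutate(
    data,
    rasb_use = .data$rasb_use | .data$novel_era | .data$novel_sglt2i,
    is_use = .data$is_use | .data$novel_nefecon | .data$novel_hcq |
      .data$novel_telitacicept
  )
}

#' Percentile risk groups from linear predictors
#'
#' Splits a cohort into the four published risk groups at the 16th, 50th and
#' 84th percentiles of the linear predictor: low (`< Q16`), intermediate
#' (`Q16 <= LP <= Q50`), higher (`Q50 < LP <= Q84`) and highest (`> Q84`).
#' Percentiles use linear interpolation at position \eqn{1 + (n-1)p} on the
#' order statistics; on tie-free linear predictors this reproduces the
#' canonical group sizes (e.g. 109/230/229/109 at n = 677).
#'
#' @param data A cohort tibble, or a bare numeric vector of linear
#'   predictors.
#' @param lp Column holding the linear predictor when `data` is a data frame.
#' @return For data-frame input, the tibble with an ordered factor column
#'   `risk_group`; for vector input, the factor itself.  Group counts are
#'   available via `table()`.
#' @export
assign_risk_groups <- function(data, lp = "lp") {
  vec_input <- is.numeric(data)
  lpv <- if (vec_input) data else data[[lp]]
  if (is.null(lpv)) abort(sprintf("no `%s` column in `data`", lp))
  n <- length(lpv)
  if (n < 4) abort("need at least 4 patients to form risk groups")
  if (any(!is.finite(lpv))) abort("non-finite linear predictor")
  if (length(unique(lpv)) == 1) {
    abort("all linear predictors identical: degenerate grouping")
  }
  qs <- interp_quantile(lpv, c(0.16, 0.50, 0.84))
  tied_boundary <- vapply(qs, function(q) sum(lpv == q) > 1, logical(1))
  if (any(tied_boundary)) {
    warn("tied linear predictors at a group boundary; printed group counts assume tie-free LPs")
  }
  labels <- risk_group_levels()
  grp <- dplyr::case_when(
    lpv < qs[1] ~ labels[1],
    lpv <= qs[2] ~ labels[2],
    lpv <= qs[3] ~ labels[3],
    TRUE ~ labels[4]
  )
  grp <- factor(grp, levels = labels, ordered = TRUE)
  if (vec_input) {
    return(grp)
  }
  dplyr::mutate(tibble::as_tibble(data), risk_group = grp)
}

#' @rdname assign_risk_groups
#' @export
risk_group_levels <- function() c("low", "intermediate", "higher", "highest")

#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' The 2009 creatinine equation with sex-specific constants and no race
#' coefficient (the no-race form is the default used for cohort curation
#' here; the race multiplier has been retired from practice).  Creatinine is
#' taken in micromol/L and converted to mg/dL by dividing by 88.4.
#'
#' @param scr_umol_L Serum creatinine, micromol/L (> 0).
#' @param age_years Age in years (> 0).
#' @param sex `"male"` or `"female"` (vectorised).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' ckd_epi_egfr(61.88, 40, "female") # at the female knot: 144 * 0.993^40
ckd_epi_egfr <- function(scr_umol_L, age_years, sex) {
  if (any(scr_umol_L <= 0) || any(age_years <= 0)) {
    abort("creatinine and age must be positive")
  }
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    abort('`sex` must be "male" or "female"')
  }
  scr <- scr_umol_L / 88.4
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.329, -0.411)
  const <- ifelse(sex == "female", 144, 141)
  const * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.209 *
    0.993^age_years
}
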
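---
title: "Validating the IIgAN-PT on novel-therapy cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the IIgAN-PT on novel-therapy cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iganpt)
library(dplyr)
```

## The problem

The International IgA Nephropathy Prediction Tool (IIgAN-PT) is a Cox-model
calculator of the risk that an IgA nephropathy patient reaches the composite
kidney outcome — a 50% decline in eGFR or end-stage kidney disease — within
80 months, from clinicopathological data at biopsy (At-biopsy model) or 1–2
years later (Post-biopsy model). It was derived in cohorts biopsied around
2006, before endothelin receptor antagonists, SGLT2 inhibitors, Nefecon,
hydroxychloroquine or telitacicept entered IgAN practice. Whether its risk
estimates still hold for patients on these novel therapies is an empirical
question, and answering it requires the standard external-validation battery
for survival prediction models: discrimination, calibration, model fit, and
risk stratification.

`iganpt` implements that battery end-to-end, together with a synthetic
cohort generator, so the whole pipeline is reproducible without patient
data. Patient-level registry data of this kind cannot be shared publicly,
which shapes two design choices discussed below: coefficient sets are
external data files, and all tests run on synthetic cohorts whose generating
process is fully known.

## The risk engine

### Linear predictor and absolute risk

A coefficient set parameterises one model variant as a list of terms
$(x_j, c_j, \beta_j)$ with a transform (identity, log, or indicator of a
categorical level). The linear predictor is the centred dot product

$$LP = \sum_j \beta_j\,\{f_j(x_j) - c_j\},$$

and, absent a time-varying race effect, the absolute risk at horizon $t$ is
$1 - S_0(t)^{\exp(LP)}$ with $S_0$ the model's baseline survival. $S_0$ is
shipped as a grid of $(t, S_0(t))$ pairs; the cumulative hazard
$H_0 = -\log S_0$ is interpolated linearly between grid points with
$H_0(0)=0$, and horizons outside the grid are an error rather than an
extrapolation.

The with-race variants carry a piecewise effect for Chinese race because the
tool's developers found the proportional-hazards assumption violated for
that covariate: the log hazard ratio is $\beta_{early}$ before 36 months and
$\beta_{late}$ after. The risk then follows from piecing together the
cumulative hazard:

$$\text{risk}(t) = 1 - \exp\!\big[-H_0(\min(t, 36))\,e^{LP+\beta_{early}}
 - \max\{0, H_0(t) - H_0(36)\}\,e^{LP+\beta_{late}}\big].$$

When $\beta_{early}=\beta_{late}$ this collapses to the plain formula with a
constant race offset, which the test-suite verifies.

### Coefficient sets are data, not code

The published tool's exact coefficients live in the supplements of its
source publications and are deliberately **not** hard-coded here. The
package ships two kinds of JSON coefficient files: a minimal `"toy"` set
used by unit tests, and a `"synthetic_reference"` family (At-/Post-biopsy,
with/without race) whose constants are *plausible stand-ins constructed for
this package* — clinically sensible signs and magnitudes (risk increases
with log-proteinuria, MAP, MEST lesions and immunosuppression history;
decreases with eGFR and age), calibrated as described under *Synthetic
cohorts*. Files and labels say "SYNTHETIC" explicitly. Anyone holding the
published constants can transcribe them into the same schema and run the
identical pipeline; nothing in the code assumes particular values.

### Risk groups and quantiles

Patients are grouped at the 16th/50th/84th percentiles of the linear
predictor into low / intermediate / higher / highest risk groups. Several
quantile conventions exist; this package fixes linear interpolation at
position $1+(n-1)p$ on the order statistics (R's type 7) with boundary rules
low $< Q_{16}$, intermediate $\le Q_{50}$, higher $\le Q_{84}$, highest
$> Q_{84}$, because on tie-free linear predictors that convention reproduces
the canonical published group sizes exactly: 109/230/229/109 at $n=677$ and
91/192/192/91 at $n=566$. Tied values at a boundary all receive the label of
the rule above, with a warning, since printed counts assume tie-free LPs.
Calibration deciles reuse the same interpolated quantiles (left-closed,
right-open bins) for internal consistency.

### Drug remapping

The tool predates the novel agents, so its only drug inputs are
RAS-blockade and immunosuppressant use. `remap_novel_drugs()` maps by
mechanism — ERAs and SGLT2 inhibitors count as RAS blockers, while Nefecon,
hydroxychloroquine and telitacicept count as immunosuppressants — leaving
the novel-drug flags themselves untouched. The operation is idempotent, and
unknown drug names in free-text input are an error rather than silently
ignored.

### eGFR

`ckd_epi_egfr()` implements the 2009 CKD-EPI creatinine equation with
sex-specific constants and *no race coefficient*: the source cohort papers
cite only "the CKD-EPI formula", and the race multiplier has been retired
from nephrology practice, so 2009/no-race is the default (the function is a
utility for cohort curation; predictions take eGFR as given).

## The validation battery

All metrics are evaluated at a 60-month horizon by default — the 5-year
risk, matching the median follow-up of the emulated cohort — and the horizon
is a parameter everywhere (the tool itself supports up to 80 months).

**Discrimination.** `chambless_c()` is the nonparametric Chambless–Diao
estimator of the cumulative/dynamic AUC at the horizon: each event time
$t_k \le t$ contributes its Kaplan–Meier mass times the empirical
probability that subjects failing at $t_k$ out-rank the subjects still under
observation beyond $t$, normalised by the KM cumulative incidence at $t$.
With no censoring this reduces *exactly* to pairwise concordance between
subjects with events by the horizon and subjects surviving past it, which is
how the test-suite checks it by enumeration. An independent IPCW
(inverse-probability-of-censoring-weighted) estimator of the same AUC,
`concordance_ipcw()`, serves as a cross-check; the two can drift apart under
heavy censoring, and the Chambless–Diao estimate is the one reported.

**Calibration slope.** The Cox coefficient of the externally computed LP as
the only covariate. Exactly 1 when the cohort's risk gradient matches the
tool; below 1 when the tool's gradient is too steep, as expected when
effective therapies compress outcome differences. The Cox machinery is the
`survival` package (Efron ties); the tests verify it against a direct grid
search of the partial likelihood, including the three-subject example whose
stationary point is $-\tfrac12\log 2$ in closed form.

**Model fit.** `royston_r2d()` ranks the LPs, replaces them by Blom-score
normal order statistics ($\Phi^{-1}\{(r-3/8)/(n+1/4)\}$; exact rankits are
indistinguishable at $n \ge 50$) scaled by $\kappa=\sqrt{8/\pi}$, takes the
Cox coefficient $D$ on that covariate, and reports
$R^2_D = (D^2/\kappa^2)/(\pi^2/6 + D^2/\kappa^2)$. For a
normally-distributed true LP with variance $\sigma^2$ this converges to
$\sigma^2/(\sigma^2 + \pi^2/6)$ — so a unit-variance LP gives
$R^2_D \approx 0.378$, an identity the acceptance suite verifies by
simulation at $n = 10\,000$.

**ICI.** The integrated calibration index is the mean absolute difference
between each subject's predicted risk and a smoothed observed risk at the
same predicted value. The smoother is a Cox model on a restricted cubic
spline (3 knots at the 10th/50th/90th percentiles; knot count configurable)
of $\log(-\log(1-\hat p))$, with the observed risk read off the Breslow
baseline hazard at the horizon. The literature defines the ICI but not the
smoother; a spline on the complementary-log-log of the prediction is the
standard choice for survival outcomes because it is linear exactly when the
predictions are proportional-hazards-correct. Predicted risks of exactly 0
or 1 are clipped to $[10^{-6}, 1-10^{-6}]$ with a warning. The smoother
recovers a constant 0.10 miscalibration offset to within 0.02 in simulation.

**Stratification.** Per risk group: Kaplan–Meier observed risk (Greenwood
variance, 95% bands on the log(−log) scale so they stay inside $[0,1]$),
mean predicted risk, Cox hazard ratios against the low-risk group, and a
trend p-value. The trend test is a Wald test on the ordinal group score
(0–3) in a separate Cox fit — the convention chosen here since published
tables print "P-value for trend" without naming a method; a score test would
be asymptotically equivalent. Zero-event groups surface as a
monotone-likelihood flag on the fit rather than a silent huge hazard ratio.

**eGFR slopes.** `fit_egfr_slopes()` fits a linear mixed model (`lme4`,
REML) to longitudinal eGFR: fixed effects for time, risk group, their
interaction and the baseline adjusters (age, sex, MAP, 24-h proteinuria,
MEST scores), with a random intercept and slope per subject. Per-group
slopes are fixed-effect contrasts with Wald 95% intervals, in
mL/min/1.73 m²/year. A singular random-slope covariance triggers a
documented fallback to a random intercept only; subjects with fewer than two
observations are dropped with a warning, and the fit requires at least three
observations for half the subjects.

## Synthetic cohorts

`generate_cohort()` emulates a contemporary Chinese novel-therapy cohort:

* **Marginals** follow the published baseline table of such a cohort:
  median age 22 (lognormal with offset 14), eGFR 76 (truncated normal, SD 34,
  bounded below at 16 since patients already in ESKD are excluded at
  biopsy), MAP 99 mmHg, proteinuria 1.4 g/day (lognormal), MEST prevalences
  M1 50.8%, E1 36.9%, S1 75.9%, T1 26.4%, T2 8.7%, RASB 33.7%,
  immunosuppressant 7.8%, male 46.2%.
* **Correlations** come from a Gaussian copula with a fixed, documented
  matrix (lower eGFR with older age, −0.35, and worse T score, −0.45; mild
  proteinuria–lesion and MAP–RASB dependence). The emulated table reports
  only marginals, so these correlations are declared assumptions, not facts.
* **Novel drugs**: every subject receives at least one novel agent (that is
  the cohort definition); the four most frequent combinations all contain
  hydroxychloroquine, and ERA/SGLT2i-only regimens carry probability 0.121
  so the ERA/SGLT2i-only subset of a 677-patient draw has expected size 82.
* **Events** are sampled by inverse-transform from the hazard
  $h(t) = \theta\,h_0(t)\,\exp(\beta_{true} LP + \beta_{race}(t))$, with
  $h_0$ Weibull (shape 1.8) and the piecewise race effect applied exactly as
  in prediction. The Weibull scale (367.9 months) was calibrated once, by
  large-sample Monte Carlo, so that the mean model-implied 5-year risk is
  9.8% — the anchor reported for the emulated cohort. The shipped
  synthetic-reference baseline survival *is* this Weibull evaluated on a
  2-month grid, so under $\theta = 1, \beta_{true} = 1$ the generator and
  the coefficient set describe the same model and predictions are perfectly
  calibrated by construction. That makes miscalibration a controlled
  experiment: $\theta = 0.5, \beta_{true} = 0.5$ encodes "novel therapies
  halve the hazard and flatten the risk gradient", and the pipeline should
  (and does) report a calibration slope near 0.5, an inflated ICI and
  predicted $>$ observed risk in the upper risk groups — the qualitative
  overestimation pattern that motivates the package.
* **Censoring**: administrative censoring uniform on 12–120 months (the
  cohort design requires at least 12 months of follow-up; the resulting
  median follow-up is about five years) plus a 2% uniform dropout. The
  emulated cohort's 28.1% cumulative event proportion over two decades of
  accrual is *not* a target of these defaults; the 5-year-risk anchor is.
* **Trajectories**: per-subject linear eGFR with the intercept at baseline
  eGFR, a true annual slope drawn per LP quartile (defaults near
  −2.5 to −2.9 mL/min/1.73 m²/year, SD 1), 6-monthly visits and visit noise
  SD 5. `reconcile_outcomes()` optionally rederives the outcome from the
  trajectory crossing of $\max(\text{eGFR}/2, 15)$, making the composite
  definition literally true of the synthetic data; the Weibull outcome is
  the default because the calibration experiments need the proportional-
  hazards generating model. Landmark (1-year) covariates are baseline values
  perturbed by the subject's slope and measurement noise, available for a
  random 86% of subjects with follow-up beyond 12 months — an explicit
  assumption standing in for re-measured clinic data.

What passing tests on these cohorts shows: the estimators recover the
generating process they were pointed at, at realistic size and censoring.
What it does not show: robustness to everything real registries add —
informative censoring, assay changes across two decades, missing-not-at-
random biopsies, measurement error in proteinuria — none of which the
generator emulates.

## Numerical and design notes

* Quantiles: type-7 interpolation everywhere, for the exact-counts property
  above.
* Percentages in reported tables use half-up rounding to one decimal
  (`pct_of()`), so 190/677 prints as 28.1.
* Internal time unit is months (the 36-month cutpoint and 80-month maximum
  are model constants); slopes convert to years at the interface.
* Cox fits: Efron tie handling by default (switchable to Breslow);
  monotone likelihood is detected both from `coxph` warnings and from
  coefficients drifting beyond ±10 on the log scale.
* KM bands: log(−log) transform; while no event has occurred the band is
  degenerate at the estimate rather than `NA`.
* `validate_predictions()` and `run_scenario()` contain no randomness:
  rerunning on the same inputs yields byte-identical report files.
* Problem sizes used by the shipped checks were chosen to make each
  statistical property sharp at desk scale: $n = 5000$ cohorts for the
  calibration experiments, $n = 10\,000$ for the $R^2_D$ identity, $n = 300$
  subjects × 11 visits for slope recovery, and $n \le 20$ for the oracle
  equivalences where exhaustive search is feasible.

## Limitations

The synthetic-reference coefficients are stand-ins; absolute risks from them
are meaningful only within the synthetic world. Scenario (iii)'s landmark
covariates are perturbed baselines, not re-measured labs. The pediatric
model variants and any re-estimation or updating of the tool's coefficients
are out of scope. The C-statistic reported is the 5-year cumulative/dynamic
AUC; it is not comparable to Harrell's C over full follow-up.
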
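#' Coefficient sets for the IIgAN-PT risk engine
#'
#' A coefficient set is the full parameterisation of one variant of the
#' International IgAN Prediction Tool: the Cox model terms (covariate,
#' transform, centering constant, coefficient), the optional piecewise
#' race-effect term (the Chinese-race hazard ratio changes at 36 months
#' because the proportional-hazards assumption is violated), and the baseline
#' survival function \eqn{S_0(t)} evaluated on a grid of months.
#'
#' Coefficient values live in data files, never in code: the package ships a
#' deliberately simple `"toy"` set used throughout the test-suite and a
#' `"synthetic_reference"` family for the At-biopsy and Post-biopsy models
#' (with and without race).  The synthetic-reference constants are plausible
#' stand-ins constructed for this package — they are *not* transcriptions of
#' the published tool and must not be used clinically.
#'
#' @param model_id `"at_biopsy"` or `"post_biopsy"`.
#' @param variant `"with_race"` or `"without_race"`.
#' @param terms A data frame with columns `covariate`, `transform`
#'   (`"identity"`, `"log"` or `"indicator"`), `level` (only used by
#'   `"indicator"` terms), `center` and `coefficient`.
#' @param race_piecewise `NULL`, or a list with elements `race`,
#'   `cutpoint_months` (36 for the published tool), `beta_early`, `beta_late`.
#' @param baseline_survival A data frame with columns `time_months` and `s0`,
#'   non-increasing in time, values in (0, 1]; must cover the evaluation
#'   horizon (60 months by default, 80 months maximum for the published tool).
#' @param label Free-text provenance label stored with the set.
#'
#' @return An object of class `iigan_coefficient_set`.
#' @export
#' @examples
#' cs <- iigan_coefficient_set("toy")
#' cs
coefficient_set <- function(model_id = c("at_biopsy", "post_biopsy"),
                            variant = c("with_race", "without_race"),
                            terms,
                            race_piecewise = NULL,
                            baseline_survival,
                            label = "unlabelled") {
  model_id <- match.arg(model_id)
  variant <- match.arg(variant)
  terms <- tibble::as_tibble(terms)
  if (!"level" %in% names(terms)) terms$level <- NA_character_
  needed <- c("covariate", "transform", "level", "center", "coefficient")
  if (!all(needed %in% names(terms))) {
    abort(paste0(
      "`terms` must have columns ",
      paste(setdiff(needed, names(terms)), collapse = ", ")
    ))
  }
  terms <- terms[, needed]
  bad_tr <- setdiff(unique(terms$transform), c("identity", "log", "indicator"))
  if (length(bad_tr)) {
    abort(paste0("unknown transform_spec: ", paste(bad_tr, collapse = ", ")))
  }
  baseline_survival <- tibble::as_tibble(baseline_survival)
  stopifnot(all(c("time_months", "s0") %in% names(baseline_survival)))
  baseline_survival <-
    baseline_survival[order(baseline_survival$time_months), ]
  s0 <- baseline_survival$s0
  if (any(s0 <= 0) || any(s0 > 1)) {
    abort("baseline survival values must lie in (0, 1]")
  }
  if (is.unsorted(rev(s0))) {
    abort("baseline survival must be non-increasing in time")
  }
  if (variant == "without_race" &&
    (!is.null(race_piecewise) || any(terms$covariate == "race"))) {
    abort("without_race variants must not carry race terms")
  }
  if (!is.null(race_piecewise)) {
    stopifnot(all(c("race", "cutpoint_months", "beta_early", "beta_late") %in%
      names(race_piecewise)))
  }
  structure(
    list(
      model_id = model_id, variant = variant, terms = terms,
      race_piecewise = race_piecewise,
      baseline_survival = baseline_survival, label = label
    ),
    class = "iigan_coefficient_set"
  )
}

#' @export
print.iigan_coefficient_set <- function(x, ...) {
  cat(sprintf(
    "<iigan_coefficient_set> %s / %s (%s)\n", x$model_id, x$variant, x$label
  ))
  cat(sprintf(
    "  %d terms; baseline survival on %d time points (max %g months)\n",
    nrow(x$terms), nrow(x$baseline_survival),
    max(x$baseline_survival$time_months)
  ))
  if (!is.null(x$race_piecewise)) {
    cat(sprintf(
      "  piecewise race effect: %s, cut %g months, beta %.3f -> %.3f\n",
      x$race_piecewise$race, x$race_piecewise$cutpoint_months,
      x$race_piecewise$beta_early, x$race_piecewise$beta_late
    ))
  }
  invisible(x)
}

#' Read / write a coefficient set as JSON
#'
#' The on-disk schema mirrors the constructor arguments:
#' `{model_id, variant, label, terms: [...], race_piecewise: {...}?,
#' baseline_survival: [...]}`.
#'
#' @param path File path.
#' @return `read_coefficient_set()` returns an `iigan_coefficient_set`;
#'   `write_coefficient_set()` returns `path` invisibly.
#' @export
read_coefficient_set <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  coefficient_set(
    model_id = x$model_id, variant = x$variant,
    terms = x$terms,
    race_piecewise = x$race_piecewise,
    baseline_survival = x$baseline_survival,
    label = x$label %||% "unlabelled"
  )
}

#' @param coeffs An `iigan_coefficient_set`.
#' @rdname read_coefficient_set
#' @export
write_coefficient_set <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "iigan_coefficient_set"))
  out <- list(
    model_id = coeffs$model_id, variant = coeffs$variant,
    label = coeffs$label, terms = coeffs$terms,
    baseline_survival = coeffs$baseline_survival
  )
  if (!is.null(coeffs$race_piecewise)) {
    out$race_piecewise <- coeffs$race_piecewise
  }
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Load a coefficient set shipped with the package
#'
#' @param which One of `"toy"`, `"synthetic_reference_at_biopsy"`,
#'   `"synthetic_reference_post_biopsy"`.
#' @param variant `"with_race"` or `"without_race"` (ignored for the toy set,
#'   which is `without_race`).
#' @return An `iigan_coefficient_set`.
#' @export
iigan_coefficient_set <- function(which = c(
                                    "toy",
                                    "synthetic_reference_at_biopsy",
                                    "synthetic_reference_post_biopsy"
                                  ),
                                  variant = c("with_race", "without_race")) {
  which <- match.arg(which)
  variant <- match.arg(variant)
  file <- switch(which,
    toy = "coeffs_toy.json",
    synthetic_reference_at_biopsy =
      sprintf("coeffs_synthetic_reference_at_biopsy_%s.json", variant),
    synthetic_reference_post_biopsy =
      sprintf("coeffs_synthetic_reference_post_biopsy_%s.json", variant)
  )
  path <- system.file("extdata", file, package = "iganpt", mustWork = TRUE)
  read_coefficient_set(path)
}
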
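#' Calibration plot (deciles of the linear predictor)
#'
#' Mean predicted 5-year risk per LP decile against the Kaplan-Meier
#' observed risk, with 95% log(-log) bands as vertical whiskers and the
#' identity line marking perfect calibration.  Points above the line are
#' deciles where the tool overestimates risk.
#'
#' @param report An `iigan_validation` object.
#' @return A ggplot object.
#' @export
plot_calibration <- function(report) {
  stopifnot(inherits(report, "iigan_validation"))
  ggplot2::ggplot(
    report$decile_table,
    ggplot2::aes(x = .data$mean_predicted_risk, y = .data$km_observed_risk)
  ) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      width = 0
    ) +
    ggplot2::geom_point() +
    ggplot2::coord_equal(
      xlim = c(0, NA), ylim = c(0, NA), expand = TRUE
    ) +
    ggplot2::labs(
      x = sprintf("Predicted %g-month risk", report$horizon_months),
      y = "Observed risk (Kaplan-Meier)",
      title = report$scenario_id
    ) +
    ggplot2::theme_minimal()
}

#' Predicted versus observed risk by risk group (bar chart)
#'
#' @inheritParams plot_calibration
#' @return A ggplot object.
#' @export
plot_group_risks <- function(report) {
  stopifnot(inherits(report, "iigan_validation"))
  long <- report$group_table |>
    dplyr::mutate(group = factor(.data$group, levels = risk_group_levels())) |>
    tidyr::pivot_longer(
      c("mean_predicted_risk", "km_observed_risk"),
      names_to = "kind", values_to = "risk"
    ) |>
    dplyr::mutate(kind = ifelse(
      .data$kind == "mean_predicted_risk", "predicted", "observed"
    ))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$group, y = .data$risk, fill = .data$kind)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(
      x = "Risk group",
      y = sprintf("%g-month risk", report$horizon_months),
      fill = NULL, title = report$scenario_id
    ) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves of the composite outcome by risk group
#'
#' @inheritParams plot_calibration
#' @return A ggplot object.
#' @export
plot_km_groups <- function(report) {
  stopifnot(inherits(report, "iigan_validation"))
  km <- report$km_groups |>
    dplyr::group_by(.data$risk_group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(
        time = 0, n_risk = max(.x$n_risk), n_event = 0L, n_censor = 0L,
        survival = 1, ci_lower = 1, ci_upper = 1
      ),
      .x
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(
    km,
    ggplot2::aes(
      x = .data$time, y = .data$survival, colour = .data$risk_group
    )
  ) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Months since biopsy", y = "Event-free survival",
      colour = "Risk group", title = report$scenario_id
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.iigan_validation <- function(object, ...) {
  plot_calibration(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
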
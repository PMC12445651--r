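#' @importFrom rlang .data abort warn %||%
#' @importFrom stats quantile qnorm pnorm setNames median approx vcov coef
#'   rnorm runif rexp rbinom sd var pchisq complete.cases
#' @importFrom utils head tail
NULL

# Interpolated quantile at position 1 + (n - 1) * p on the order statistics
# (stats::quantile type 7).  All percentile machinery in the package (risk
# groups, calibration deciles) goes through this one helper so the convention
# cannot drift between callers.
interp_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

# Half-up rounding (5 always rounds away from zero), used for reported
# percentages so that printed tables match clinical-journal style.
round_half_up <- function(x, digits = 1) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# Format a count as "n (pct%)" with one-decimal half-up percentage.
fmt_count_pct <- function(n, total) {
  pct <- if (total > 0) round_half_up(100 * n / total, 1) else 0
  sprintf("%d (%.1f)", n, pct)
}

# Complementary log-log of a risk (probability of the event by the horizon).
cloglog <- function(p) log(-log(1 - p))

# Clip probabilities away from 0/1 before cloglog; warn when clipping occurs.
clip_prob <- function(p, eps = 1e-6) {
  out_of_range <- p <= 0 | p >= 1
  if (any(out_of_range)) {
    warn(sprintf(
      "%d predicted risk(s) of exactly 0 or 1 clipped to [%.0e, 1 - %.0e]",
      sum(out_of_range), eps, eps
    ))
  }
  pmin(pmax(p, eps), 1 - eps)
}

# Restricted cubic spline basis (Harrell parameterisation): k knots give
# k - 1 columns, linear in the tails.  Used by the ICI smoother.
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3)
  tk <- knots[k]
  tk1 <- knots[k - 1]
  scale <- (tk - knots[1])^2
  pp <- function(u) pmax(u, 0)^3
  basis <- matrix(0, length(x), k - 1)
  basis[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    basis[, j + 1] <- (pp(x - tj) -
      pp(x - tk1) * (tk - tj) / (tk - tk1) +
      pp(x - tk) * (tk1 - tj) / (tk - tk1)) / scale
  }
  basis
}

# Draw n samples from MVN(0, R) given a correlation matrix R.
rmvnorm_chol <- function(n, R) {
  L <- chol(R)
  z <- matrix(stats::rnorm(n * ncol(R)), n, ncol(R))
  z %*% L
}

# Quantile transform of a standard-normal draw onto a truncated normal.
qtruncnorm_from_z <- function(z, mean, sd, lower, upper) {
  a <- stats::pnorm((lower - mean) / sd)
  b <- stats::pnorm((upper - mean) / sd)
  u <- a + stats::pnorm(z) * (b - a)
  mean + sd * stats::qnorm(u)
}

#' Percentage of a count, journal style
#'
#' One-decimal half-up percentage of `n` out of `total`, the rounding used in
#' every reported table (so 190/677 prints as 28.1).
#'
#' @param n Count.
#' @param total Denominator.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @export
pct_of <- function(n, total, digits = 1) {
  round_half_up(100 * n / total, digits)
}
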
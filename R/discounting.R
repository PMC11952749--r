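# Apparent temporal discounting of a reward-rate-optimal agent.

default_delay_grid <- function(outside) {
  seq(0, 4 * outside$outside_time, length.out = 41L)
}

#' Apparent temporal discounting function
#'
#' The magnitude-normalised subjective value of an outcome `r` as a function
#' of the delay `t` required to obtain it,
#' `D(t) = (1 - rho_out * t / r) / (1 + t / t_out)`,
#' which is exactly `sv(r, t) / r` with the subjective value from
#' [subjective_value_in_out()]. The hyperbolic curvature is set by
#' `1 / t_out` (the apportionment of time) and the linear term in the
#' numerator by the outside rate (the opportunity cost); when the outside
#' rate is zero the curve is the pure hyperbola `1 / (1 + t / t_out)`.
#' Negative values are reported as-is: they mark delays at which the
#' pursuit should be forgone if possible.
#'
#' @param outcome Outcome magnitude `r` (non-zero; negative for a
#'   punishment).
#' @param outside An [outside_context()].
#' @param delays Non-negative delay grid; defaults to 41 points on
#'   `[0, 4 * t_out]`.
#' @return An object of class `discount_curve`: a list with `delays`,
#'   `values` (dimensionless discount factors, 1 at zero delay), `sv` (the
#'   unnormalised subjective values), `outcome` and `outside`.
#' @examples
#' dc <- discount_function(5, outside_context(0.5 * 5, 5))
#' dc$values[dc$delays == 5]
#' @export
discount_function <- function(outcome, outside,
                              delays = default_delay_grid(outside)) {
  stopifnot(is.numeric(outcome), length(outcome) == 1L, is.finite(outcome),
            inherits(outside, "outside_context"),
            is.numeric(delays), all(is.finite(delays)), all(delays >= 0))
  if (outcome == 0)
    stop("outcome must be non-zero to normalise a discounting function")
  sv <- sv_time_curve(outcome, outside, delays)$sv
  structure(list(delays = as.numeric(delays), values = sv / outcome,
                 sv = sv, outcome = outcome, outside = outside),
            class = "discount_curve")
}

#' @export
print.discount_curve <- function(x, ...) {
  cat(sprintf(
    "<discount_curve> outcome %g, rho_out %g, t_out %g; %d delays on [%g, %g]\n",
    x$outcome, outside_rate(x$outside), x$outside$outside_time,
    length(x$delays), min(x$delays), max(x$delays)))
  invisible(x)
}

#' @export
as.data.frame.discount_curve <- function(x, ...) {
  data.frame(delay = x$delays, sv = x$sv, discount_value = x$values)
}

#' Subjective value as a function of delay
#'
#' Evaluates `sv(r, t)` over a grid of delays, treating the delay as the
#' pursuit's full duration. With a positive outside rate the curve crosses
#' zero at `t = r / rho_out`; with zero outside rate it stays positive and
#' decays hyperbolically to zero.
#'
#' @inheritParams discount_function
#' @return A data frame with columns `delay` and `sv`.
#' @examples
#' sv_time_curve(4, outside_context(0.7, 3), delays = c(0, 4, 20))
#' @export
sv_time_curve <- function(outcome, outside,
                          delays = default_delay_grid(outside)) {
  stopifnot(is.numeric(outcome), length(outcome) == 1L, is.finite(outcome),
            inherits(outside, "outside_context"),
            is.numeric(delays), all(is.finite(delays)), all(delays >= 0))
  t_out <- outside$outside_time
  rho_out <- outside_rate(outside)
  sv <- (outcome - rho_out * delays) * (t_out / (delays + t_out))
  data.frame(delay = as.numeric(delays), sv = sv)
}

#' Fit the standard hyperbolic discount parameter k
#'
#' Least-squares fit of the standard hyperbolic discounting function
#' `1 / (1 + k t)` to a discount curve, on the value scale, with `k >= 0`.
#' For a curve generated with zero outside rate the fit recovers
#' `k = 1 / t_out` exactly; curves with positive outside rate force the
#' hyperbola to absorb the unmodelled opportunity cost, inflating `k`.
#'
#' @param curve A [discount_function()] result with at least three distinct
#'   delays.
#' @return The fitted `k` (per time unit).
#' @examples
#' fit_hyperbolic_k(discount_function(1, outside_context(0, 5)))  # 0.2
#' @export
fit_hyperbolic_k <- function(curve) {
  stopifnot(inherits(curve, "discount_curve"))
  if (length(unique(curve$delays)) < 3L)
    stop("need at least three distinct delays to fit k")
  if (diff(range(curve$values)) == 0)
    stop("degenerate (constant) discount curve: cannot fit k")
  sse <- function(k) sum((curve$values - 1 / (1 + k * curve$delays))^2)
  t_pos <- curve$delays[curve$delays > 0]
  k_hi <- max(1, 100 / min(t_pos))
  fit <- stats::optimize(sse, interval = c(0, k_hi), tol = 1e-12)
  # boundary check: sse is smooth, but guard the k = 0 corner
  if (sse(0) <= fit$objective) 0 else fit$minimum
}

#' Magnitude-effect construction
#'
#' Discount curves for a small and a large reward in the same context. With
#' a positive outside rate the large-reward curve lies strictly above the
#' small-reward curve at every positive delay (apparent discounting is
#' shallower for larger rewards); with zero outside rate the two curves
#' coincide and the effect vanishes.
#'
#' @param r_small,r_large Reward magnitudes, `0 < r_small < r_large`.
#' @inheritParams discount_function
#' @return A list with `small` and `large` [discount_function()] curves.
#' @examples
#' mc <- magnitude_effect_curves(2, 5, outside_context(0.5 * 5, 5))
#' @export
magnitude_effect_curves <- function(r_small, r_large, outside,
                                    delays = default_delay_grid(outside)) {
  stopifnot(is.numeric(r_small), is.numeric(r_large),
            r_small > 0, r_large > r_small)
  list(small = discount_function(r_small, outside, delays),
       large = discount_function(r_large, outside, delays))
}

#' Sign-effect construction
#'
#' Discount curves for a reward and a punishment of equal magnitude. With a
#' positive outside rate the punishment appears to discount less steeply
#' than the reward; the curves coincide at zero outside rate, and the
#' ordering inverts when the outside rate is negative (a net-punishing
#' outside).
#'
#' @param magnitude Common outcome magnitude (positive); the reward curve
#'   uses `+magnitude`, the punishment curve `-magnitude`.
#' @inheritParams discount_function
#' @return A list with `reward` and `punishment` [discount_function()]
#'   curves.
#' @examples
#' sc <- sign_effect_curves(3, outside_context(0.5 * 5, 5))
#' @export
sign_effect_curves <- function(magnitude, outside,
                               delays = default_delay_grid(outside)) {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L, magnitude > 0)
  list(reward = discount_function(magnitude, outside, delays),
       punishment = discount_function(-magnitude, outside, delays))
}
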
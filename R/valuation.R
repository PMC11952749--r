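# Subjective value of initiating a pursuit and the decomposition of time's
# cost into opportunity and apportionment components.

#' Subjective value from a known global reward rate
#'
#' The subjective value of a pursuit is the immediate reward magnitude whose
#' acceptance yields the same global reward rate as investing `t_in` and
#' collecting `r_in`: `sv = r_in - rho_g * t_in`, i.e. the pursuit's reward
#' less the cost of its time at the global rate attained under a policy of
#' accepting it.
#'
#' @param p The considered [pursuit()].
#' @param global_rate Global reward rate under a policy of accepting the
#'   pursuit.
#' @return The subjective value (reward units).
#' @examples
#' p <- pursuit(4, 4)
#' subjective_value_from_global_rate(p, global_rate = 4.7 / 7)
#' @export
subjective_value_from_global_rate <- function(p, global_rate) {
  stopifnot(inherits(p, "pursuit"), is.numeric(global_rate),
            length(global_rate) == 1L, is.finite(global_rate))
  p$reward - global_rate * p$duration
}

#' Subjective value and time-cost decomposition from the pursuit's outside
#'
#' Computes the subjective value in the in/outside form
#' `sv = (r_in - rho_out * t_in) * (t_out / (t_in + t_out))`
#' -- the opportunity-cost-subtracted reward downscaled by the apportionment
#' of time spent outside the pursuit -- together with the full decomposition
#' of time's cost. The two ingredients of time's cost are the opportunity
#' cost `rho_out * t_in` (reward expected under a policy of *not* taking the
#' pursuit over its duration) and the apportionment cost
#' `t_in * (rho_g - rho_out)` (the extra average reward a policy of taking
#' versus not taking the pursuit yields over its duration). They sum to
#' `rho_g * t_in`, and the subjective value here agrees identically with
#' [subjective_value_from_global_rate()] evaluated at the in/outside global
#' rate.
#'
#' A pursuit of zero duration is legal and has `sv = r_in` with zero time
#' cost: subjective value is defined as an immediate-reward equivalent.
#'
#' @param p The considered [pursuit()].
#' @param outside Its [outside_context()] (`outside_time > 0`).
#' @return An object of class `valuation_breakdown`: a list with fields
#'   `subjective_value`, `global_rate`, `occupancy_weight`, `time_cost`,
#'   `opportunity_cost`, `apportionment_cost`.
#' @examples
#' subjective_value_in_out(pursuit(4, 4), outside_context(0.7, 3))
#' @export
subjective_value_in_out <- function(p, outside) {
  stopifnot(inherits(p, "pursuit"), inherits(outside, "outside_context"))
  t_in <- p$duration
  t_out <- outside$outside_time
  rho_out <- outside_rate(outside)
  rho_g <- global_rate_in_out(p, outside)
  sv <- (p$reward - rho_out * t_in) * (t_out / (t_in + t_out))
  structure(list(subjective_value = sv,
                 global_rate = rho_g,
                 occupancy_weight = occupancy_weight(p, outside),
                 time_cost = rho_g * t_in,
                 opportunity_cost = rho_out * t_in,
                 apportionment_cost = t_in * (rho_g - rho_out),
                 pursuit = p,
                 outside = outside),
            class = "valuation_breakdown")
}

#' @export
print.valuation_breakdown <- function(x, ...) {
  cat("<valuation_breakdown>\n")
  cat(sprintf("  subjective value   : %.6g\n", x$subjective_value))
  cat(sprintf("  global reward rate : %.6g\n", x$global_rate))
  cat(sprintf("  occupancy weight   : %.6g\n", x$occupancy_weight))
  cat(sprintf("  time cost          : %.6g\n", x$time_cost))
  cat(sprintf("    opportunity cost : %.6g\n", x$opportunity_cost))
  cat(sprintf("    apportionment    : %.6g\n", x$apportionment_cost))
  invisible(x)
}

#' @export
as.data.frame.valuation_breakdown <- function(x, ...) {
  data.frame(subjective_value = x$subjective_value,
             global_rate = x$global_rate,
             occupancy_weight = x$occupancy_weight,
             time_cost = x$time_cost,
             opportunity_cost = x$opportunity_cost,
             apportionment_cost = x$apportionment_cost)
}

#' Subjective value of a non-exclusive pursuit
#'
#' When engaging in a pursuit does not exclude the agent from continuing to
#' collect reward at the rate prevailing outside it, the opportunity cost of
#' time drops out and the value of initiating the pursuit reduces to
#' `sv = r_in / (1 + t_in / t_out)`, independent of the outside reward. This
#' coincides with [subjective_value_in_out()] when the outside reward is
#' zero.
#'
#' @inheritParams subjective_value_in_out
#' @return The subjective value (reward units).
#' @examples
#' subjective_value_nonexclusive(pursuit(4, 4), outside_context(0.7, 3))
#' @export
subjective_value_nonexclusive <- function(p, outside) {
  stopifnot(inherits(p, "pursuit"), inherits(outside, "outside_context"))
  p$reward / (1 + p$duration / outside$outside_time)
}
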
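# Reward-rate-optimal Forgo and Choice policies, critical thresholds and
# policy-region maps.

#' Forgo decision for a single offered pursuit
#'
#' Take the pursuit when its local rate exceeds the outside rate, forgo when
#' it falls below, and treat the two policies as equivalent when the rates
#' are equal (within `tol`). The decision agrees with the sign of the
#' pursuit's subjective value.
#'
#' @param p The offered [pursuit()] (`duration > 0`).
#' @param outside Its [outside_context()].
#' @param tol Absolute indifference tolerance on rates.
#' @return One of `"take"`, `"forgo"`, `"indifferent"`.
#' @examples
#' forgo_decision(pursuit(2.5, 2.5), outside_context(0.8 * 6, 6))  # take
#' forgo_decision(pursuit(2.5, 2.5), outside_context(1.3 * 6, 6))  # forgo
#' @export
forgo_decision <- function(p, outside, tol = 1e-9) {
  stopifnot(inherits(p, "pursuit"), inherits(outside, "outside_context"))
  compare_rates(local_rate(p), outside_rate(outside), tol,
                c("take", "forgo", "indifferent"))
}

compare_rates <- function(a, b, tol, labels) {
  if (a > b + tol) labels[1]
  else if (a < b - tol) labels[2]
  else labels[3]
}

#' Reward-rate-optimal accept set for a forgo world
#'
#' Finds the accept policy maximising the global reward rate by iteratively
#' discarding accepted pursuits whose local rate falls below their current
#' outside rate (the global rate of the policy that drops them), until no
#' pursuit violates the rule. At each step the lowest-rate violating pursuit
#' is removed first (ties broken by index) so the procedure is
#' deterministic; the final set is independent of removal order and attains
#' the maximum of [global_rate_forgo_world()] over all subsets (see
#' [brute_force_optimal_accept_set()] for the exhaustive cross-check).
#'
#' @param world A [forgo_world()].
#' @param tol Absolute indifference tolerance on rates; pursuits whose rate
#'   matches their outside rate within `tol` are kept (taking and forgoing
#'   are then equivalent).
#' @return Sorted integer vector of accepted pursuit indices, with the
#'   attained global rate in attribute `"rate"`.
#' @examples
#' w <- forgo_world(list(pursuit(1, 1), pursuit(0.2, 1)), c(1, 1), 0)
#' optimal_accept_set(w)  # keeps only the first pursuit
#' @export
optimal_accept_set <- function(world, tol = 1e-9) {
  stopifnot(inherits(world, "forgo_world"))
  accept <- seq_along(world$pursuits)
  rates <- vapply(world$pursuits, local_rate, numeric(1))
  repeat {
    if (length(accept) == 0L) break
    out_rates <- vapply(accept, function(i) {
      outside_rate(parcel_world(world, accept, i)$outside)
    }, numeric(1))
    violating <- accept[rates[accept] < out_rates - tol]
    if (length(violating) == 0L) break
    drop <- violating[order(rates[violating], violating)][1]
    accept <- setdiff(accept, drop)
  }
  structure(accept, rate = global_rate_forgo_world(world, accept))
}

#' Choice between a smaller-sooner and a larger-later pursuit
#'
#' Selects the pursuit whose acceptance policy yields the larger global
#' reward rate given a shared outside context. This is equivalent to the
#' marginal-rate rule -- choose LL when
#' `(r_LL - r_SS) / (t_LL - t_SS)` exceeds the attained optimal global rate
#' -- and to comparing the pursuits' subjective values.
#'
#' @param ss The smaller-sooner [pursuit()].
#' @param ll The larger-later [pursuit()].
#' @param outside Shared [outside_context()].
#' @param tol Absolute indifference tolerance on rates.
#' @return One of `"SS"`, `"LL"`, `"indifferent"`.
#' @examples
#' ss <- pursuit(2.5, 2.5); ll <- pursuit(5, 8.5)
#' choice_decision(ss, ll, outside_context(0, 6))        # LL
#' choice_decision(ss, ll, outside_context(0.4 * 6, 6))  # SS
#' @export
choice_decision <- function(ss, ll, outside, tol = 1e-9) {
  stopifnot(inherits(ss, "pursuit"), inherits(ll, "pursuit"),
            inherits(outside, "outside_context"))
  rate_ss <- global_rate_in_out(ss, outside)
  rate_ll <- global_rate_in_out(ll, outside)
  compare_rates(rate_ll, rate_ss, tol, c("LL", "SS", "indifferent"))
}

#' Behavior triplet: choice plus both forgo decisions
#'
#' Evaluates the three decisions an agent faces about a smaller-sooner and a
#' larger-later pursuit sharing an outside context: the choice between them,
#' and whether to take or forgo each one offered alone. With a
#' [misestimation_spec()], every comparison is made with the agent's
#' *perceived* quantities: global rates from [misestimated_global_rate()],
#' and forgo comparisons between perceived local and perceived outside
#' rates.
#'
#' @inheritParams choice_decision
#' @param misestimation Optional [misestimation_spec()]; `NULL` means a
#'   veridical agent.
#' @return An object of class `behavior_triplet` with fields `choice`
#'   (`"SS"`/`"LL"`/`"indifferent"`), `forgo_ll` and `forgo_ss`
#'   (`"take"`/`"forgo"`/`"indifferent"`).
#' @examples
#' ss <- pursuit(2.5, 2.5); ll <- pursuit(5, 8.5)
#' behavior_triplet(ss, ll, outside_context(0.8 * 6, 6))
#' @export
behavior_triplet <- function(ss, ll, outside, misestimation = NULL,
                             tol = 1e-9) {
  stopifnot(inherits(ss, "pursuit"), inherits(ll, "pursuit"),
            inherits(outside, "outside_context"))
  if (is.null(misestimation))
    misestimation <- misestimation_spec("none")
  stopifnot(inherits(misestimation, "misestimation_spec"))
  rate_ss <- misestimated_global_rate(ss, outside, misestimation)
  rate_ll <- misestimated_global_rate(ll, outside, misestimation)
  choice <- compare_rates(rate_ll, rate_ss, tol, c("LL", "SS", "indifferent"))
  rho_out_hat <- misestimated_outside_rate(outside, misestimation)
  fg <- function(p) {
    compare_rates(misestimated_local_rate(p, misestimation), rho_out_hat,
                  tol, c("take", "forgo", "indifferent"))
  }
  structure(list(choice = choice, forgo_ll = fg(ll), forgo_ss = fg(ss)),
            class = "behavior_triplet")
}

#' @export
print.behavior_triplet <- function(x, ...) {
  cat(sprintf("<behavior_triplet> choose %s, %s LL, %s SS\n",
              x$choice, x$forgo_ll, x$forgo_ss))
  invisible(x)
}

#' @export
format.behavior_triplet <- function(x, ...) {
  paste(x$choice, x$forgo_ll, x$forgo_ss, sep = "/")
}

#' Critical outside reward rate for a choice preference switch
#'
#' The outside reward rate at which the global rates under the choose-SS and
#' choose-LL policies are equal, holding the outside time fixed. Solving
#' `(r_SS + rho * t_out) / (t_SS + t_out) = (r_LL + rho * t_out) / (t_LL + t_out)`
#' for `rho` gives the closed form
#' `(r_LL t_SS - r_SS t_LL + t_out (r_LL - r_SS)) / (t_out (t_LL - t_SS))`.
#' Below it the LL pursuit is preferred, above it the SS pursuit (when the
#' SS pursuit has the higher local rate).
#'
#' @inheritParams choice_decision
#' @param t_out Outside time (held fixed while the outside rate varies).
#' @return The critical outside rate, or `NA` if no crossing exists at a
#'   non-negative rate.
#' @examples
#' critical_outside_rate_for_choice(pursuit(2.5, 2.5), pursuit(5, 8.5), 6)
#' @export
critical_outside_rate_for_choice <- function(ss, ll, t_out) {
  stopifnot(inherits(ss, "pursuit"), inherits(ll, "pursuit"),
            is.numeric(t_out), length(t_out) == 1L, t_out > 0)
  dt <- ll$duration - ss$duration
  if (dt == 0)
    stop("pursuit durations must differ for an outside-rate crossing")
  rho <- (ll$reward * ss$duration - ss$reward * ll$duration +
            t_out * (ll$reward - ss$reward)) / (t_out * dt)
  if (!is.finite(rho) || rho < 0) NA_real_ else rho
}

#' Critical outside time for a choice preference switch
#'
#' The outside time at which the subjective values of the SS and LL pursuits
#' become equal, holding the outside reward per traversal fixed (so the
#' outside rate falls as the outside time grows). The root of
#' `sv_SS(t_out) - sv_LL(t_out)` is bracketed on `(t_min, t_max)` and
#' refined by bisection to an interval narrower than `1e-10`.
#'
#' @inheritParams choice_decision
#' @param r_out Outside reward per traversal, held fixed.
#' @param t_min,t_max Search interval for the bracketing scan.
#' @return The critical outside time, or `NA` if the difference does not
#'   change sign on the interval.
#' @examples
#' critical_outside_time_for_choice(pursuit(2, 3), pursuit(5, 12.6),
#'                                  r_out = 0.5)
#' @export
critical_outside_time_for_choice <- function(ss, ll, r_out,
                                             t_min = 1e-6, t_max = 1e6) {
  stopifnot(inherits(ss, "pursuit"), inherits(ll, "pursuit"),
            is.numeric(r_out), length(r_out) == 1L, is.finite(r_out),
            t_min > 0, t_max > t_min)
  gap <- function(t_out) {
    o <- outside_context(r_out, t_out)
    subjective_value_in_out(ss, o)$subjective_value -
      subjective_value_in_out(ll, o)$subjective_value
  }
  grid <- exp(seq(log(t_min), log(t_max), length.out = 200L))
  vals <- vapply(grid, gap, numeric(1))
  if (all(abs(vals) < 1e-14)) return(NA_real_)  # everywhere indifferent
  flip <- which(vals[-1] * vals[-length(vals)] <= 0 &
                  (vals[-1] != 0 | vals[-length(vals)] != 0))
  if (length(flip) == 0L) return(NA_real_)
  stats::uniroot(gap, lower = grid[flip[1]], upper = grid[flip[1] + 1L],
                 tol = 1e-12)$root
}

#' Delay at which choice preference reverses from SS to LL
#'
#' The Delay Effect: a common delay `d` prepended to both pursuits lowers
#' the global rate of every policy while the marginal rate between the
#' pursuits stays fixed, so an agent that initially prefers the
#' smaller-sooner pursuit switches to the larger-later one at a critical
#' delay. The delay lies on the path common to both policies -- i.e. outside
#' either considered pursuit -- and accrues no reward. For a veridical agent
#' (`omega = 1`) the reversal delay solves
#' `(r_SS + r_out) / (t_SS + t_out + d) = (r_LL + r_out) / (t_LL + t_out + d)`.
#' With `omega != 1` the agent misweights all outside time, the common delay
#' included, while preserving the outside rate (the malapportionment agent),
#' and the same linear equation is solved in the perceived quantities
#' `omega * (t_out + d)` and `omega * r_out`.
#'
#' @inheritParams choice_decision
#' @param omega Apportionment weight applied to outside time and reward;
#'   `1` is the veridical agent, values below 1 underweight the outside.
#' @return The reversal delay `d`, or `NA` when no reversal exists (the SS
#'   pursuit is not preferred at zero delay, or the root is not positive).
#' @examples
#' ss <- pursuit(2, 3); ll <- pursuit(5, 12.6)
#' preference_reversal_delay(ss, ll, outside_context(2.5, 5))  # 6.4
#' @export
preference_reversal_delay <- function(ss, ll, outside, omega = 1) {
  stopifnot(inherits(ss, "pursuit"), inherits(ll, "pursuit"),
            inherits(outside, "outside_context"),
            is.numeric(omega), length(omega) == 1L, omega > 0)
  a <- ss$reward + omega * outside$outside_reward
  b <- ll$reward + omega * outside$outside_reward
  if (b <= a) return(NA_real_)  # LL never gains from extra delay
  # perceived outside time at the reversal, u = omega * (t_out + d)
  u <- (a * ll$duration - b * ss$duration) / (b - a)
  d <- u / omega - outside$outside_time
  if (!is.finite(d) || d <= 0) return(NA_real_)
  # require SS preferred at zero delay under the same perceived quantities
  rate_ss0 <- a / (ss$duration + omega * outside$outside_time)
  rate_ll0 <- b / (ll$duration + omega * outside$outside_time)
  if (rate_ss0 <= rate_ll0) return(NA_real_)
  d
}

#' Policy-region map over outside rate and misestimation error
#'
#' Evaluates the [behavior_triplet()] on a grid of outside reward rates
#' (x) and misestimation magnitudes `omega` (y) for a fixed outside time,
#' and locates the boundary rates separating adjacent distinct triplets in
#' each row by bisection. The row at `omega = 1` (or with variable
#' `"none"`) reproduces the veridical agent's map.
#'
#' @inheritParams choice_decision
#' @param t_out Outside time (fixed across the map).
#' @param outside_rate_grid Sorted vector of outside reward rates.
#' @param misestimation_variable One of the variable tags accepted by
#'   [misestimation_spec()]; `"none"` gives the veridical agent for every
#'   row.
#' @param omega_grid Vector of error magnitudes, one row each.
#' @return An object of class `policy_region_map`: a list with `map` (long
#'   data frame: `outside_rate`, `omega`, `choice`, `forgo_ll`, `forgo_ss`)
#'   and `boundaries` (data frame: `omega`, `boundary_rate`, `from`, `to`,
#'   with triplets formatted `choice/forgo_ll/forgo_ss`).
#' @examples
#' m <- policy_region_map(pursuit(2.5, 2.5), pursuit(5, 8.5), t_out = 6,
#'                        outside_rate_grid = c(0, 0.4, 0.8, 1.3))
#' m$map
#' @export
policy_region_map <- function(ss, ll, t_out, outside_rate_grid,
                              misestimation_variable = "none",
                              omega_grid = 1, tol = 1e-9) {
  stopifnot(inherits(ss, "pursuit"), inherits(ll, "pursuit"),
            is.numeric(t_out), t_out > 0,
            is.numeric(outside_rate_grid), !is.unsorted(outside_rate_grid),
            is.numeric(omega_grid), all(omega_grid > 0))
  cell <- function(rho, omega) {
    outside <- make_outside(rho, t_out)
    spec <- misestimation_spec(misestimation_variable, omega)
    behavior_triplet(ss, ll, outside, spec, tol = tol)
  }
  rows <- list(); bnds <- list()
  for (omega in omega_grid) {
    trips <- lapply(outside_rate_grid, cell, omega = omega)
    labs <- vapply(trips, format, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      outside_rate = outside_rate_grid, omega = omega,
      choice = vapply(trips, `[[`, character(1), "choice"),
      forgo_ll = vapply(trips, `[[`, character(1), "forgo_ll"),
      forgo_ss = vapply(trips, `[[`, character(1), "forgo_ss"),
      stringsAsFactors = FALSE)
    for (j in which(labs[-1] != labs[-length(labs)])) {
      lo <- outside_rate_grid[j]; hi <- outside_rate_grid[j + 1L]
      for (k in 1:60) {  # bisect on the first change of triplet label
        mid <- (lo + hi) / 2
        if (format(cell(mid, omega)) == labs[j]) lo <- mid else hi <- mid
      }
      bnds[[length(bnds) + 1L]] <- data.frame(
        omega = omega, boundary_rate = (lo + hi) / 2,
        from = labs[j], to = labs[j + 1L], stringsAsFactors = FALSE)
    }
  }
  structure(list(map = do.call(rbind, rows),
                 boundaries = if (length(bnds)) do.call(rbind, bnds) else
                   data.frame(omega = numeric(), boundary_rate = numeric(),
                              from = character(), to = character())),
            class = "policy_region_map")
}

#' @export
print.policy_region_map <- function(x, ...) {
  cat(sprintf("<policy_region_map> %d cells, %d boundaries\n",
              nrow(x$map), nrow(x$boundaries)))
  print(utils::head(x$map, 12))
  invisible(x)
}

# outside context at a given outside *rate* for a fixed outside time;
# degenerate rate 0 is representable since rewards may be zero
make_outside <- function(rho_out, t_out) {
  outside_context(rho_out * t_out, t_out)
}
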
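# Data model for temporal decision-making worlds built from recurrent pursuits.

#' Create a pursuit
#'
#' A pursuit is a path through the world that requires a fixed time
#' investment and yields a reward (possibly negative, i.e. a punishment),
#' after which the agent re-enters the rest of the world. Its local reward
#' rate is always derived as `reward / duration` and never stored, so the
#' three quantities cannot drift apart.
#'
#' @param reward Reward magnitude obtained on completing the pursuit
#'   (reward units; any sign).
#' @param duration Time the pursuit occupies (time units; must be
#'   non-negative, and strictly positive wherever a local rate is needed).
#' @param label Optional identifier used in printing and CSV output.
#'
#' @return An object of class `pursuit`.
#' @examples
#' p <- pursuit(reward = 4, duration = 4)
#' local_rate(p)
#' @export
pursuit <- function(reward, duration, label = NULL) {
  stopifnot(is.numeric(reward), length(reward) == 1L, is.finite(reward),
            is.numeric(duration), length(duration) == 1L, is.finite(duration))
  if (duration < 0)
    stop("pursuit duration must be non-negative, got ", duration)
  structure(list(reward = as.numeric(reward),
                 duration = as.numeric(duration),
                 label = label),
            class = "pursuit")
}

#' @export
print.pursuit <- function(x, ...) {
  lbl <- if (is.null(x$label)) "" else paste0(" '", x$label, "'")
  cat(sprintf("<pursuit%s> reward %g over %g time units", lbl,
              x$reward, x$duration))
  if (x$duration > 0) cat(sprintf(" (rate %g)", x$reward / x$duration))
  cat("\n")
  invisible(x)
}

#' Local reward rate of a pursuit
#'
#' @param p A [pursuit()].
#' @return `reward / duration`.
#' @export
local_rate <- function(p) {
  stopifnot(inherits(p, "pursuit"))
  if (p$duration <= 0)
    stop("local rate undefined: pursuit duration must be positive")
  p$reward / p$duration
}

#' Create a forgo world
#'
#' A forgo world consists of `n` pursuit types encountered at random from a
#' default pursuit. While in the default pursuit the agent accrues reward at
#' rate `default_rate` and encounters pursuit `i` at frequency
#' `frequencies[i]` per unit default-pursuit time; frequencies are
#' interpreted as Poisson encounter rates.
#'
#' @param pursuits A list of [pursuit()] objects (all durations strictly
#'   positive).
#' @param frequencies Numeric vector of strictly positive encounter rates,
#'   one per pursuit (events per unit default-pursuit time).
#' @param default_rate Reward rate accrued while in the default pursuit
#'   (reward units per unit default time).
#'
#' @return An object of class `forgo_world`.
#' @examples
#' w <- forgo_world(list(pursuit(2, 1), pursuit(4, 2)),
#'                  frequencies = c(0.5, 0.25), default_rate = 0)
#' global_rate_forgo_world(w, accept_set = c(1, 2))
#' @export
forgo_world <- function(pursuits, frequencies = numeric(), default_rate = 0) {
  if (inherits(pursuits, "pursuit")) pursuits <- list(pursuits)
  stopifnot(is.list(pursuits),
            all(vapply(pursuits, inherits, logical(1), "pursuit")),
            is.numeric(frequencies),
            is.numeric(default_rate), length(default_rate) == 1L,
            is.finite(default_rate))
  if (length(frequencies) != length(pursuits))
    stop("need one encounter frequency per pursuit (got ",
         length(frequencies), " for ", length(pursuits), " pursuits)")
  if (length(frequencies) && any(frequencies <= 0))
    stop("encounter frequencies must be strictly positive")
  durs <- vapply(pursuits, `[[`, numeric(1), "duration")
  if (length(durs) && any(durs <= 0))
    stop("all pursuit durations in a forgo world must be strictly positive")
  structure(list(pursuits = pursuits,
                 frequencies = as.numeric(frequencies),
                 default_rate = as.numeric(default_rate)),
            class = "forgo_world")
}

#' @export
print.forgo_world <- function(x, ...) {
  cat(sprintf("<forgo_world> %d pursuit type(s), default rate %g\n",
              length(x$pursuits), x$default_rate))
  for (i in seq_along(x$pursuits)) {
    p <- x$pursuits[[i]]
    cat(sprintf("  [%d] r = %g, t = %g, f = %g%s\n", i, p$reward, p$duration,
                x$frequencies[i],
                if (is.null(p$label)) "" else paste0("  (", p$label, ")")))
  }
  invisible(x)
}

#' Create an outside context
#'
#' Everything outside a considered pursuit type, summarised as the average
#' reward `outside_reward` collected and the average time `outside_time`
#' spent outside the pursuit for each traversal through it. The outside
#' reward rate is derived as `outside_reward / outside_time`.
#'
#' @param outside_reward Average reward per traversal obtained outside the
#'   considered pursuit (any sign).
#' @param outside_time Average time per traversal spent outside the
#'   considered pursuit (strictly positive).
#'
#' @return An object of class `outside_context`.
#' @examples
#' outside_context(outside_reward = 0.7, outside_time = 3)
#' @export
outside_context <- function(outside_reward, outside_time) {
  stopifnot(is.numeric(outside_reward), length(outside_reward) == 1L,
            is.finite(outside_reward),
            is.numeric(outside_time), length(outside_time) == 1L,
            is.finite(outside_time))
  if (outside_time <= 0)
    stop("outside_time must be strictly positive, got ", outside_time)
  structure(list(outside_reward = as.numeric(outside_reward),
                 outside_time = as.numeric(outside_time)),
            class = "outside_context")
}

#' @export
print.outside_context <- function(x, ...) {
  cat(sprintf("<outside_context> reward %g over %g time units (rate %g)\n",
              x$outside_reward, x$outside_time, outside_rate(x)))
  invisible(x)
}

#' Outside reward rate
#'
#' @param outside An [outside_context()].
#' @return `outside_reward / outside_time`.
#' @export
outside_rate <- function(outside) {
  stopifnot(inherits(outside, "outside_context"))
  outside$outside_reward / outside$outside_time
}

check_accept_set <- function(world, accept_set) {
  n <- length(world$pursuits)
  accept_set <- as.integer(accept_set)
  if (anyNA(accept_set) || any(accept_set < 1L) || any(accept_set > n))
    stop("accept_set must be a subset of pursuit indices 1..", n)
  sort(unique(accept_set))
}

#' Global reward rate of a forgo world under an accept policy
#'
#' The long-run reward rate attained by an agent that accepts every
#' encountered pursuit in `accept_set` and rejects all others. Rejected
#' pursuits contribute neither reward nor time. With `f_i` the encounter
#' frequencies, `r_i`/`t_i` the accepted pursuits' rewards and durations and
#' `rho_d` the default rate, the rate is
#' `(sum(f_i * r_i) + rho_d) / (sum(f_i * t_i) + 1)`, the expectation of a
#' renewal process normalised to one unit of default-pursuit time.
#'
#' @param world A [forgo_world()].
#' @param accept_set Integer indices of the accepted pursuit types (may be
#'   empty; defaults to accepting everything).
#' @return The global reward rate (reward units per time unit).
#' @examples
#' w <- forgo_world(list(pursuit(4, 4)), frequencies = 1 / 3,
#'                  default_rate = 7 / 30)
#' global_rate_forgo_world(w, 1)
#' @export
global_rate_forgo_world <- function(world, accept_set = seq_along(world$pursuits)) {
  stopifnot(inherits(world, "forgo_world"))
  accept_set <- check_accept_set(world, accept_set)
  if (length(accept_set) == 0L)
    return(world$default_rate)
  f <- world$frequencies[accept_set]
  r <- vapply(world$pursuits[accept_set], `[[`, numeric(1), "reward")
  t <- vapply(world$pursuits[accept_set], `[[`, numeric(1), "duration")
  if (any(t <= 0))
    stop("accepted pursuits must have strictly positive durations")
  (sum(f * r) + world$default_rate) / (sum(f * t) + 1)
}

#' Parcel a forgo world into a focal pursuit and its outside
#'
#' Re-expresses the world, under a given accept policy, from the perspective
#' of one accepted (focal) pursuit type: everything else is summarised as the
#' average time spent and reward collected outside the focal pursuit per
#' traversal through it,
#' `t_out = (sum_{i != focal} f_i t_i + 1) / f_focal` and
#' `r_out = (sum_{i != focal} f_i r_i + rho_d) / f_focal`.
#' The in/outside global rate of the result reproduces the direct
#' forgo-world rate exactly (see [global_rate_in_out()]).
#'
#' @inheritParams global_rate_forgo_world
#' @param focal Index of the focal pursuit; must be in `accept_set`.
#' @return A list with elements `pursuit` (the focal [pursuit()], unchanged)
#'   and `outside` (an [outside_context()]).
#' @examples
#' w <- forgo_world(list(pursuit(4, 4)), frequencies = 1 / 3,
#'                  default_rate = 7 / 30)
#' parcel_world(w, accept_set = 1, focal = 1)
#' @export
parcel_world <- function(world, accept_set = seq_along(world$pursuits), focal) {
  stopifnot(inherits(world, "forgo_world"))
  accept_set <- check_accept_set(world, accept_set)
  focal <- as.integer(focal)
  if (length(focal) != 1L || !(focal %in% accept_set))
    stop("focal pursuit must be a single index contained in accept_set")
  others <- setdiff(accept_set, focal)
  f <- world$frequencies
  r <- vapply(world$pursuits, `[[`, numeric(1), "reward")
  t <- vapply(world$pursuits, `[[`, numeric(1), "duration")
  t_out <- (sum(f[others] * t[others]) + 1) / f[focal]
  r_out <- (sum(f[others] * r[others]) + world$default_rate) / f[focal]
  list(pursuit = world$pursuits[[focal]],
       outside = outside_context(r_out, t_out))
}

#' Global reward rate from the in/outside parcellation
#'
#' The reward rate of the environment under a policy of accepting the
#' considered pursuit, expressed with the world parcelled into the pursuit
#' and everything outside it: `(r_in + r_out) / (t_in + t_out)`.
#'
#' @param p The considered [pursuit()].
#' @param outside Its [outside_context()].
#' @return The global reward rate.
#' @examples
#' global_rate_in_out(pursuit(4, 4), outside_context(0.7, 3))  # 4.7 / 7
#' @export
global_rate_in_out <- function(p, outside) {
  stopifnot(inherits(p, "pursuit"), inherits(outside, "outside_context"))
  tot <- p$duration + outside$outside_time
  if (tot <= 0)
    stop("total traversal time must be positive")
  (p$reward + outside$outside_reward) / tot
}

#' Occupancy weight of a pursuit
#'
#' Fraction of traversal time invested in the considered pursuit,
#' `w_in = t_in / (t_in + t_out)`. The global rate is the
#' occupancy-weighted average of the local rates:
#' `w_in * rho_in + (1 - w_in) * rho_out`.
#'
#' @inheritParams global_rate_in_out
#' @return A fraction in `[0, 1)`.
#' @examples
#' occupancy_weight(pursuit(4, 4), outside_context(0.7, 3))  # 4/7
#' @export
occupancy_weight <- function(p, outside) {
  stopifnot(inherits(p, "pursuit"), inherits(outside, "outside_context"))
  p$duration / (p$duration + outside$outside_time)
}
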
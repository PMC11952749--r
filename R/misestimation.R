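# Parameter-misestimation agents: six single-variable error models and the
# malapportionment agent that misweights time while preserving rates.

MISESTIMATION_VARIABLES <- c("none",
                             "outside_time", "outside_reward",
                             "outside_both_rate_preserved",
                             "inside_time", "inside_reward",
                             "inside_both_rate_preserved")

#' Specify a misestimated variable and its error magnitude
#'
#' A misestimating agent multiplies one variable of the global-reward-rate
#' computation by an error term `omega` (`omega < 1` underestimation,
#' `omega > 1` overestimation, `omega = 1` veridical). The
#' `*_both_rate_preserved` variants scale a side's reward and time together
#' so the perceived reward *rate* of that side stays true; the variant
#' `"outside_both_rate_preserved"` with `omega < 1` is the malapportionment
#' agent (equivalently `"inside_both_rate_preserved"` with `1 / omega`).
#'
#' @param variable One of `"none"`, `"outside_time"`, `"outside_reward"`,
#'   `"outside_both_rate_preserved"`, `"inside_time"`, `"inside_reward"`,
#'   `"inside_both_rate_preserved"`.
#' @param omega Positive multiplicative error.
#' @return An object of class `misestimation_spec`.
#' @examples
#' misestimation_spec("outside_both_rate_preserved", omega = 0.5)
#' @export
misestimation_spec <- function(variable = "none", omega = 1) {
  variable <- match.arg(variable, MISESTIMATION_VARIABLES)
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega))
  if (omega <= 0) stop("omega must be strictly positive, got ", omega)
  structure(list(variable = variable, omega = as.numeric(omega)),
            class = "misestimation_spec")
}

#' @export
print.misestimation_spec <- function(x, ...) {
  cat(sprintf("<misestimation_spec> %s, omega = %g\n", x$variable, x$omega))
  invisible(x)
}

#' Misestimated global reward rate
#'
#' The global reward rate as perceived by an agent whose estimate of one
#' variable is scaled by `omega`. Writing `r_out = rho_out * t_out`, the
#' perceived rate is `(r_in + r_out) / (t_in + omega * t_out)` when outside
#' time is misestimated, `(r_in + omega * r_out) / (t_in + t_out)` for
#' outside reward, `(r_in + omega * r_out) / (t_in + omega * t_out)` for
#' both (outside rate preserved), and symmetrically for the inside
#' variants. With `omega = 1` or variable `"none"` this is the true
#' in/outside rate.
#'
#' @param p The considered [pursuit()].
#' @param outside Its [outside_context()].
#' @param spec A [misestimation_spec()].
#' @return The perceived global reward rate.
#' @examples
#' misestimated_global_rate(pursuit(2, 2.5), outside_context(3, 10),
#'                          misestimation_spec("outside_time", 0.5))
#' @export
misestimated_global_rate <- function(p, outside, spec) {
  stopifnot(inherits(p, "pursuit"), inherits(outside, "outside_context"),
            inherits(spec, "misestimation_spec"))
  r_in <- p$reward; t_in <- p$duration
  r_out <- outside$outside_reward; t_out <- outside$outside_time
  w <- spec$omega
  switch(spec$variable,
         none = (r_in + r_out) / (t_in + t_out),
         outside_time = (r_in + r_out) / (t_in + w * t_out),
         outside_reward = (r_in + w * r_out) / (t_in + t_out),
         outside_both_rate_preserved =
           (r_in + w * r_out) / (t_in + w * t_out),
         inside_time = (r_in + r_out) / (w * t_in + t_out),
         inside_reward = (w * r_in + r_out) / (t_in + t_out),
         inside_both_rate_preserved =
           (w * r_in + r_out) / (w * t_in + t_out))
}

#' Misestimated outside reward rate
#'
#' The outside rate as perceived by the agent: misestimating outside time
#' scales it to `rho_out / omega`, misestimating outside reward to
#' `omega * rho_out`; the rate-preserving variants and the inside variants
#' leave it unchanged. Forgo comparisons of a misestimating agent use this
#' perceived rate.
#'
#' @inheritParams misestimated_global_rate
#' @return The perceived outside rate.
#' @examples
#' misestimated_outside_rate(outside_context(3, 10),
#'                           misestimation_spec("outside_time", 0.5))
#' @export
misestimated_outside_rate <- function(outside, spec) {
  stopifnot(inherits(outside, "outside_context"),
            inherits(spec, "misestimation_spec"))
  rho <- outside_rate(outside)
  switch(spec$variable,
         outside_time = rho / spec$omega,
         outside_reward = spec$omega * rho,
         rho)
}

#' Misestimated local (inside) reward rate
#'
#' The considered pursuit's own rate as perceived by the agent:
#' `rho_in / omega` under inside-time error, `omega * rho_in` under
#' inside-reward error, unchanged otherwise.
#'
#' @inheritParams misestimated_global_rate
#' @return The perceived local rate.
#' @export
misestimated_local_rate <- function(p, spec) {
  stopifnot(inherits(p, "pursuit"), inherits(spec, "misestimation_spec"))
  rho <- local_rate(p)
  switch(spec$variable,
         inside_time = rho / spec$omega,
         inside_reward = spec$omega * rho,
         rho)
}

#' Predictions of the malapportionment agent
#'
#' Bundles the four behavioral signatures of an agent that underweights the
#' apportionment of time outside relative to inside a pursuit while
#' correctly estimating both reward rates (`omega < 1` scales perceived
#' outside time and reward together). Each perceived quantity is computed
#' by substituting the scaled outside `omega * t_out`, `omega * r_out` into
#' the veridical operation:
#' \itemize{
#'   \item `discount`: perceived discounting of the LL reward has greater
#'     curvature than optimal;
#'   \item `magnitude`: the Magnitude-effect gap between the small and
#'     large reward curves is smaller than optimal;
#'   \item `sign`: the Sign-effect gap between punishment and reward curves
#'     is smaller than optimal;
#'   \item `reversal`: the Delay-effect preference reversal occurs at a
#'     delay larger than optimal (see [preference_reversal_delay()]).
#' }
#' At `omega = 1` every prediction coincides with the veridical agent's.
#'
#' @param ss,ll Smaller-sooner and larger-later [pursuit()]s.
#' @param outside Shared true [outside_context()].
#' @param omega Apportionment weight in `(0, 1]` for the canonical
#'   direction of the hypothesis (values above 1 are allowed and invert the
#'   predictions).
#' @param delays Delay grid for the curves; defaults to 41 points on
#'   `[0, 4 * t_out]`.
#' @param sign_magnitude Outcome magnitude used for the sign-effect pair;
#'   defaults to the SS reward.
#' @return An object of class `malapportionment_prediction`: a list with
#'   data frames `discount`, `magnitude`, `sign` (each with optimal and
#'   perceived values per delay) and `reversal` (optimal and perceived
#'   reversal delays), plus `omega`.
#' @examples
#' mp <- malapportionment_curves(pursuit(2, 3), pursuit(5, 12.6),
#'                               outside_context(2.5, 5), omega = 0.5)
#' mp$reversal
#' @export
malapportionment_curves <- function(ss, ll, outside, omega,
                                    delays = default_delay_grid(outside),
                                    sign_magnitude = abs(ss$reward)) {
  stopifnot(inherits(ss, "pursuit"), inherits(ll, "pursuit"),
            inherits(outside, "outside_context"),
            is.numeric(omega), length(omega) == 1L)
  if (omega <= 0) stop("omega must be strictly positive, got ", omega)
  perceived <- outside_context(omega * outside$outside_reward,
                               omega * outside$outside_time)
  dc <- function(outcome, ctx) discount_function(outcome, ctx, delays)$values
  discount <- data.frame(delay = delays,
                         optimal = dc(ll$reward, outside),
                         perceived = dc(ll$reward, perceived))
  magnitude <- data.frame(delay = delays,
                          optimal_small = dc(ss$reward, outside),
                          optimal_large = dc(ll$reward, outside),
                          perceived_small = dc(ss$reward, perceived),
                          perceived_large = dc(ll$reward, perceived))
  magnitude$optimal_gap <- magnitude$optimal_large - magnitude$optimal_small
  magnitude$perceived_gap <-
    magnitude$perceived_large - magnitude$perceived_small
  sign <- data.frame(delay = delays,
                     optimal_reward = dc(sign_magnitude, outside),
                     optimal_punishment = dc(-sign_magnitude, outside),
                     perceived_reward = dc(sign_magnitude, perceived),
                     perceived_punishment = dc(-sign_magnitude, perceived))
  sign$optimal_gap <- sign$optimal_punishment - sign$optimal_reward
  sign$perceived_gap <- sign$perceived_punishment - sign$perceived_reward
  reversal <- list(optimal = preference_reversal_delay(ss, ll, outside),
                   perceived = preference_reversal_delay(ss, ll, outside,
                                                         omega = omega))
  structure(list(discount = discount, magnitude = magnitude, sign = sign,
                 reversal = reversal, omega = omega),
            class = "malapportionment_prediction")
}

#' @export
print.malapportionment_prediction <- function(x, ...) {
  cat(sprintf("<malapportionment_prediction> omega = %g\n", x$omega))
  mid <- ceiling(nrow(x$discount) / 2)
  cat(sprintf("  discount value at t = %.3g : optimal %.4g, perceived %.4g\n",
              x$discount$delay[mid], x$discount$optimal[mid],
              x$discount$perceived[mid]))
  cat(sprintf("  magnitude gap (mean)      : optimal %.4g, perceived %.4g\n",
              mean(x$magnitude$optimal_gap), mean(x$magnitude$perceived_gap)))
  cat(sprintf("  sign gap (mean)           : optimal %.4g, perceived %.4g\n",
              mean(x$sign$optimal_gap), mean(x$sign$perceived_gap)))
  cat(sprintf("  reversal delay            : optimal %.4g, perceived %.4g\n",
              x$reversal$optimal, x$reversal$perceived))
  invisible(x)
}
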
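# Independent oracles: stochastic world traversal and exhaustive policy
# enumeration.

#' Simulate traversals of a forgo world
#'
#' Monte-Carlo renewal process matching the analytic global-rate formula:
#' the agent waits in the default pursuit for an exponential time with rate
#' `sum(f_i)` (accruing the default rate), then encounters pursuit `i` with
#' probability `f_i / sum(f_j)`. Accepted encounters add their reward and
#' duration; rejected encounters vanish without cost (opportunities arriving
#' mid-pursuit are discarded, not queued). The empirical rate
#' `total_reward / total_time` estimates the analytic rate; its standard
#' error is computed by batch means over 100 consecutive batches to respect
#' renewal correlation.
#'
#' @param world A [forgo_world()] with at least one pursuit.
#' @param accept_set Indices of accepted pursuit types (may be empty).
#' @param n_encounters Number of encounters to simulate (>= 1).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @return An object of class `simulation_result` with fields
#'   `total_reward`, `total_time`, `empirical_rate`, `standard_error`,
#'   `n_encounters`, `seed`.
#' @examples
#' w <- forgo_world(list(pursuit(2, 1), pursuit(4, 2)), c(0.5, 0.25), 0)
#' simulate_traversals(w, accept_set = 1:2, n_encounters = 1000, seed = 1)
#' @export
simulate_traversals <- function(world, accept_set, n_encounters, seed = 0L) {
  stopifnot(inherits(world, "forgo_world"),
            is.numeric(n_encounters), length(n_encounters) == 1L,
            n_encounters >= 1)
  accept_set <- check_accept_set(world, accept_set)
  f <- world$frequencies
  if (length(f) == 0L || sum(f) <= 0)
    stop("simulation requires at least one pursuit with positive frequency")
  n <- as.integer(n_encounters)
  set.seed(as.integer(seed))
  waits <- stats::rexp(n, rate = sum(f))
  types <- sample.int(length(f), n, replace = TRUE, prob = f / sum(f))
  accepted <- types %in% accept_set
  r <- vapply(world$pursuits, `[[`, numeric(1), "reward")
  t <- vapply(world$pursuits, `[[`, numeric(1), "duration")
  enc_reward <- world$default_rate * waits + ifelse(accepted, r[types], 0)
  enc_time <- waits + ifelse(accepted, t[types], 0)
  total_reward <- sum(enc_reward)
  total_time <- sum(enc_time)
  n_batches <- min(100L, n)
  batch <- sort(rep_len(seq_len(n_batches), n))
  batch_rate <- tapply(enc_reward, batch, sum) / tapply(enc_time, batch, sum)
  se <- if (n_batches > 1) stats::sd(batch_rate) / sqrt(n_batches) else NA_real_
  structure(list(total_reward = total_reward,
                 total_time = total_time,
                 empirical_rate = total_reward / total_time,
                 standard_error = se,
                 n_encounters = n,
                 seed = as.integer(seed)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d encounters (seed %d): rate %.6g +/- %.2g (SE)\n",
    x$n_encounters, x$seed, x$empirical_rate, x$standard_error))
  invisible(x)
}

#' Exhaustive search for the reward-rate-optimal accept set
#'
#' Evaluates [global_rate_forgo_world()] over all `2^n` accept subsets and
#' returns the maximiser; ties are broken toward the smaller subset, then
#' lexicographically. Serves as the brute-force oracle for
#' [optimal_accept_set()] and is limited to `n <= 20` pursuits.
#'
#' @param world A [forgo_world()].
#' @return A list with `accept_set` (sorted indices) and `rate`.
#' @examples
#' w <- forgo_world(list(pursuit(1, 1), pursuit(0.2, 1)), c(1, 1), 0)
#' brute_force_optimal_accept_set(w)
#' @export
brute_force_optimal_accept_set <- function(world) {
  stopifnot(inherits(world, "forgo_world"))
  n <- length(world$pursuits)
  if (n > 20L)
    stop("exhaustive search refused for n > 20 pursuits (2^n subsets)")
  if (n == 0L)
    return(list(accept_set = integer(), rate = world$default_rate))
  f <- world$frequencies
  r <- vapply(world$pursuits, `[[`, numeric(1), "reward")
  t <- vapply(world$pursuits, `[[`, numeric(1), "duration")
  # subset membership matrix: row = subset, column = pursuit
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  rates <- (m %*% (f * r) + world$default_rate) / (m %*% (f * t) + 1)
  sizes <- rowSums(m)
  # lexicographic key: prefer subsets whose earliest differing index is absent
  lex <- m %*% (2^(seq_len(n) - 1))
  ord <- order(-rates, sizes, lex)
  best <- ord[1]
  list(accept_set = unname(which(m[best, ])), rate = as.numeric(rates[best]))
}
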
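# Choice/forgo threshold helpers: the true outside rate (with fixed outside
# time) at which the perceived comparison flips.
choice_threshold <- function(ss, ll, t_out, spec, upper = 5) {
  uniroot(function(rho) {
    o <- outside_context(rho * t_out, t_out)
    misestimated_global_rate(ll, o, spec) -
      misestimated_global_rate(ss, o, spec)
  }, lower = 0, upper = upper, tol = 1e-12)$root
}

forgo_threshold <- function(p, t_out, spec, upper = 5) {
  uniroot(function(rho) {
    o <- outside_context(rho * t_out, t_out)
    misestimated_local_rate(p, spec) - misestimated_outside_rate(o, spec)
  }, lower = 0, upper = upper, tol = 1e-12)$root
}

ss_m <- pursuit(2, 2.5)
ll_m <- pursuit(4.75, 8)

test_that("misestimated global rates follow the error-model formulas", {
  p <- pursuit(2, 2.5); o <- outside_context(3, 10)
  expect_equal(misestimated_global_rate(p, o, misestimation_spec("outside_time", 0.5)),
               (2 + 3) / (2.5 + 5))
  expect_equal(misestimated_global_rate(p, o, misestimation_spec("outside_reward", 0.5)),
               (2 + 1.5) / 12.5)
  expect_equal(misestimated_global_rate(p, o, misestimation_spec("outside_both_rate_preserved", 0.5)),
               (2 + 1.5) / 7.5)
  expect_equal(misestimated_global_rate(p, o, misestimation_spec("inside_time", 2)),
               (2 + 3) / 15)
  expect_equal(misestimated_global_rate(p, o, misestimation_spec("inside_reward", 2)),
               (4 + 3) / 12.5)
  expect_equal(misestimated_global_rate(p, o, misestimation_spec("inside_both_rate_preserved", 2)),
               (4 + 3) / 15)
  expect_error(misestimation_spec("outside_time", 0), "positive")
  expect_error(misestimation_spec("something_else"))
})

test_that("unit error reduces every variant to the veridical agent", {
  for (seed in 1:50) {
    pr <- random_pair(seed + 4000)
    truth <- global_rate_in_out(pr$p, pr$o)
    for (v in c("none", "outside_time", "outside_reward",
                "outside_both_rate_preserved", "inside_time",
                "inside_reward", "inside_both_rate_preserved")) {
      spec <- misestimation_spec(v, 1)
      expect_equal(misestimated_global_rate(pr$p, pr$o, spec), truth,
                   tolerance = 1e-12)
      expect_equal(misestimated_outside_rate(pr$o, spec),
                   outside_rate(pr$o), tolerance = 1e-12)
      expect_equal(misestimated_local_rate(pr$p, spec), local_rate(pr$p),
                   tolerance = 1e-12)
    }
  }
})

test_that("perceived outside rate distorts only under one-sided outside error", {
  o <- outside_context(3, 10)  # rate 0.3
  expect_equal(misestimated_outside_rate(o, misestimation_spec("outside_time", 0.5)),
               0.6)
  expect_equal(misestimated_outside_rate(o, misestimation_spec("outside_reward", 0.5)),
               0.15)
  for (w in c(0.3, 0.7, 1.6)) {
    expect_equal(misestimated_outside_rate(o, misestimation_spec("outside_both_rate_preserved", w)),
                 0.3)
    expect_equal(misestimated_outside_rate(o, misestimation_spec("inside_time", w)),
                 0.3)
  }
})

test_that("rate-preserving misweighting flips choice while forgo stays optimal", {
  o <- outside_context(0.3 * 10, 10)
  mal <- misestimation_spec("outside_both_rate_preserved", 0.3)
  expect_equal(format(behavior_triplet(ss_m, ll_m, o)), "LL/take/take")
  expect_equal(format(behavior_triplet(ss_m, ll_m, o, mal)), "SS/take/take")
})

test_that("single-variable errors distort a forgo threshold; rate-preserving errors do not", {
  t_out <- 10
  opt <- misestimation_spec("none")
  choice_opt <- choice_threshold(ss_m, ll_m, t_out, opt)
  forgo_ll_opt <- forgo_threshold(ll_m, t_out, opt)
  forgo_ss_opt <- forgo_threshold(ss_m, t_out, opt)
  expect_equal(choice_opt, 0.425, tolerance = 1e-9)
  expect_equal(forgo_ll_opt, 4.75 / 8, tolerance = 1e-9)
  expect_equal(forgo_ss_opt, 0.8, tolerance = 1e-9)

  impatient <- list(misestimation_spec("outside_time", 0.5),
                    misestimation_spec("outside_reward", 1.5),
                    misestimation_spec("inside_time", 1.5),
                    misestimation_spec("inside_reward", 0.5))
  for (spec in impatient) {
    expect_lt(choice_threshold(ss_m, ll_m, t_out, spec), choice_opt)
    distorted <-
      abs(forgo_threshold(ll_m, t_out, spec) - forgo_ll_opt) > 1e-6 ||
      abs(forgo_threshold(ss_m, t_out, spec) - forgo_ss_opt) > 1e-6
    expect_true(distorted)
  }
  for (w in c(0.3, 0.5, 0.8)) {
    for (v in c("outside_both_rate_preserved", "inside_both_rate_preserved")) {
      spec <- misestimation_spec(v, if (v == "inside_both_rate_preserved") 1 / w else w)
      expect_lt(choice_threshold(ss_m, ll_m, t_out, spec), choice_opt)
      expect_equal(forgo_threshold(ll_m, t_out, spec), forgo_ll_opt,
                   tolerance = 1e-9)
      expect_equal(forgo_threshold(ss_m, t_out, spec), forgo_ss_opt,
                   tolerance = 1e-9)
    }
  }
  # choice threshold is nondecreasing in omega up to the veridical value
  ths <- vapply(c(0.3, 0.5, 0.8, 1), function(w) {
    choice_threshold(ss_m, ll_m, t_out,
                     misestimation_spec("outside_both_rate_preserved", w))
  }, numeric(1))
  expect_true(all(diff(ths) > 0))
  expect_equal(ths[4], choice_opt, tolerance = 1e-9)
})

test_that("misestimated rows of the policy map keep forgo columns optimal", {
  grid <- seq(0, 1.2, by = 0.05)
  m <- policy_region_map(ss_m, ll_m, t_out = 10, outside_rate_grid = grid,
                         misestimation_variable = "outside_both_rate_preserved",
                         omega_grid = c(0.3, 0.6, 1))
  opt <- m$map[m$map$omega == 1, ]
  for (w in c(0.3, 0.6)) {
    row <- m$map[m$map$omega == w, ]
    expect_equal(row$forgo_ll, opt$forgo_ll)
    expect_equal(row$forgo_ss, opt$forgo_ss)
    # impatience: SS chosen wherever the veridical agent chooses SS, and more
    expect_true(all(row$choice[opt$choice == "SS"] == "SS"))
    expect_gt(sum(row$choice == "SS"), sum(opt$choice == "SS"))
  }
})

test_that("malapportionment predictions reduce to the veridical agent at unit weight", {
  mp <- malapportionment_curves(pursuit(2, 3), pursuit(5, 12.6),
                                outside_context(2.5, 5), omega = 1,
                                sign_magnitude = 3)
  expect_equal(mp$discount$perceived, mp$discount$optimal)
  expect_equal(mp$magnitude$perceived_gap, mp$magnitude$optimal_gap)
  expect_equal(mp$sign$perceived_gap, mp$sign$optimal_gap)
  expect_equal(mp$reversal$perceived, mp$reversal$optimal)
})

test_that("underweighting the outside steepens discounting, shrinks the magnitude and sign effects and defers the reversal", {
  ss <- pursuit(2, 3); ll <- pursuit(5, 12.6)
  o <- outside_context(2.5, 5)  # outside rate 0.5
  delays <- seq(0.5, 9.5, length.out = 19)  # within the positive-sv range
  mp <- malapportionment_curves(ss, ll, o, omega = 0.5, delays = delays,
                                sign_magnitude = 3)
  # greater curvature: perceived values fall below optimal at every delay
  expect_true(all(mp$discount$perceived < mp$discount$optimal))
  # both apparent effects are attenuated pointwise
  expect_true(all(mp$magnitude$perceived_gap < mp$magnitude$optimal_gap))
  expect_true(all(mp$magnitude$perceived_gap > 0))
  expect_true(all(mp$sign$perceived_gap < mp$sign$optimal_gap))
  expect_true(all(mp$sign$perceived_gap > 0))
  # delay effect is more pronounced, increasingly so with underweighting
  expect_equal(mp$reversal$optimal, 6.4)
  expect_equal(mp$reversal$perceived, 9.8)
  d_hat <- vapply(c(0.3, 0.5, 0.8, 1), function(w) {
    preference_reversal_delay(ss, ll, o, omega = w)
  }, numeric(1))
  expect_true(all(diff(d_hat) < 0))
  expect_true(all(d_hat[1:3] > d_hat[4]))
})
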
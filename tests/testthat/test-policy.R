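# Fixed choice instance: smaller-sooner 2.5 after 2.5, larger-later 5 after
# 8.5, outside time 6 (the canonical policy-transition demonstration).
ss_demo <- pursuit(2.5, 2.5)
ll_demo <- pursuit(5, 8.5)
out_at <- function(rho) outside_context(rho * 6, 6)

test_that("forgo decisions compare local and outside rates", {
  expect_equal(forgo_decision(ss_demo, out_at(0.8)), "take")
  expect_equal(forgo_decision(ss_demo, out_at(1.3)), "forgo")
  expect_equal(forgo_decision(pursuit(2, 2), outside_context(3, 3)),
               "indifferent")
})

test_that("forgo decision agrees with the sign of subjective value", {
  map <- c(take = 1, forgo = -1, indifferent = 0)
  for (seed in 1:200) {
    pr <- random_pair(seed + 2000)
    dec <- forgo_decision(pr$p, pr$o)
    sv <- subjective_value_in_out(pr$p, pr$o)$subjective_value
    if (dec != "indifferent") expect_equal(map[[dec]], sign(sv))
  }
})

test_that("iterative accept-set pruning finds the enumerated optimum", {
  w <- forgo_world(list(pursuit(1, 1), pursuit(0.2, 1)), c(1, 1), 0)
  acc <- optimal_accept_set(w)
  expect_equal(as.integer(acc), 1L)
  expect_equal(attr(acc, "rate"), 0.5)
  expect_equal(brute_force_optimal_accept_set(w),
               list(accept_set = 1L, rate = 0.5))
  # a lone profitable pursuit is always accepted over an empty default
  w1 <- forgo_world(list(pursuit(3, 2)), 0.4, 0)
  expect_equal(as.integer(optimal_accept_set(w1)), 1L)
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(1:8, 1)
    w <- generate_random_world(n, seed = seed * 13L)
    bf <- brute_force_optimal_accept_set(w)
    it <- optimal_accept_set(w)
    expect_equal(as.integer(it), bf$accept_set)
    expect_equal(attr(it, "rate"), bf$rate, tolerance = 1e-12)
  }
})

test_that("choice follows the policy with the larger global rate", {
  expect_equal(choice_decision(ss_demo, ll_demo, out_at(0)), "LL")
  expect_equal(choice_decision(ss_demo, ll_demo, out_at(0.4)), "SS")
  expect_equal(choice_decision(ss_demo, ss_demo, out_at(0.4)), "indifferent")
})

test_that("rate, marginal-rate and sv choice rules coincide", {
  for (seed in 1:300) {
    ch <- random_choice(seed)
    by_rate <- choice_decision(ch$ss, ch$ll, ch$o)
    marginal <- (ch$ll$reward - ch$ss$reward) /
      (ch$ll$duration - ch$ss$duration)
    best <- max(global_rate_in_out(ch$ss, ch$o),
                global_rate_in_out(ch$ll, ch$o))
    by_marginal <- if (marginal > best + 1e-9) "LL"
      else if (marginal < best - 1e-9) "SS" else "indifferent"
    sv_ss <- subjective_value_in_out(ch$ss, ch$o)$subjective_value
    sv_ll <- subjective_value_in_out(ch$ll, ch$o)$subjective_value
    by_sv <- if (sv_ll > sv_ss + 1e-9) "LL"
      else if (sv_ll < sv_ss - 1e-9) "SS" else "indifferent"
    expect_equal(by_marginal, by_rate)
    expect_equal(by_sv, by_rate)
  }
})

test_that("behavior triplets traverse the canonical transition sequence", {
  labs <- vapply(c(0, 0.4, 0.8, 1.3), function(rho) {
    format(behavior_triplet(ss_demo, ll_demo, out_at(rho)))
  }, character(1))
  expect_equal(labs, c("LL/take/take", "SS/take/take",
                       "SS/forgo/take", "SS/forgo/forgo"))
})

test_that("critical outside rate marks the choice switch", {
  rho_c <- critical_outside_rate_for_choice(ss_demo, ll_demo, t_out = 6)
  expect_equal(rho_c, 6.25 / 36)
  expect_equal(choice_decision(ss_demo, ll_demo, out_at(rho_c - 1e-6)), "LL")
  expect_equal(choice_decision(ss_demo, ll_demo, out_at(rho_c + 1e-6)), "SS")
  # equal rewards: no crossing at a positive outside rate
  expect_true(is.na(critical_outside_rate_for_choice(pursuit(3, 2),
                                                     pursuit(3, 5), 6)))
  expect_error(critical_outside_rate_for_choice(pursuit(1, 2), pursuit(2, 2), 6),
               "durations must differ")
})

test_that("critical outside time equalises the subjective values", {
  ss <- pursuit(2, 3); ll <- pursuit(5, 12.6)
  t_c <- critical_outside_time_for_choice(ss, ll, r_out = 0.5)
  o <- outside_context(0.5, t_c)
  expect_equal(subjective_value_in_out(ss, o)$subjective_value,
               subjective_value_in_out(ll, o)$subjective_value,
               tolerance = 1e-9)
  # closed form when the outside yields no reward
  t_c0 <- critical_outside_time_for_choice(ss, ll, r_out = 0)
  expect_equal(t_c0, (ll$reward * ss$duration - ss$reward * ll$duration) /
                 (ss$reward - ll$reward), tolerance = 1e-8)
  # identical pursuits never cross
  expect_true(is.na(critical_outside_time_for_choice(ss, ss, r_out = 0.5)))
})

test_that("preference reverses from SS to LL at the computed delay", {
  ss <- pursuit(2, 3); ll <- pursuit(5, 12.6)
  o <- outside_context(2.5, 5)
  d <- preference_reversal_delay(ss, ll, o)
  expect_equal(d, 6.4)
  # for the veridical agent the common delay is interchangeable with
  # lengthening both pursuits: the choice flips across d
  delayed <- function(p, d) pursuit(p$reward, p$duration + d)
  expect_equal(choice_decision(delayed(ss, d - 0.01), delayed(ll, d - 0.01), o),
               "SS")
  expect_equal(choice_decision(delayed(ss, d + 0.01), delayed(ll, d + 0.01), o),
               "LL")
  # equal rewards: LL never becomes preferred
  expect_true(is.na(preference_reversal_delay(pursuit(2, 3), pursuit(2, 9), o)))
})

test_that("the optimal policy map transitions in the canonical order", {
  m <- policy_region_map(ss_demo, ll_demo, t_out = 6,
                         outside_rate_grid = c(0, 0.4, 0.8, 1.3))
  labs <- paste(m$map$choice, m$map$forgo_ll, m$map$forgo_ss, sep = "/")
  expect_equal(labs, c("LL/take/take", "SS/take/take",
                       "SS/forgo/take", "SS/forgo/forgo"))
  expect_equal(m$boundaries$boundary_rate, c(6.25 / 36, 5 / 8.5, 1),
               tolerance = 1e-6)
  # dense sweep: transitions happen once each, in order
  # offset grid keeps clear of exact indifference points (e.g. rate 1.0)
  dense <- policy_region_map(ss_demo, ll_demo, 6, seq(0.005, 1.495, by = 0.01))
  seqs <- rle(paste(dense$map$choice, dense$map$forgo_ll, dense$map$forgo_ss,
                    sep = "/"))$values
  expect_equal(seqs, c("LL/take/take", "SS/take/take",
                       "SS/forgo/take", "SS/forgo/forgo"))
})
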
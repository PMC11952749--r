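# Random fixtures for property-style tests. All draws are seeded by the
# caller so runs are reproducible.

# a random (pursuit, outside) pair with strictly positive times
random_pair <- function(seed) {
  set.seed(seed)
  list(p = pursuit(runif(1, -5, 10), runif(1, 0.1, 10)),
       o = outside_context(runif(1, -5, 10), runif(1, 0.1, 10)))
}

# vectorised draws of valuation inputs for bulk identity checks
random_pair_frame <- function(n, seed) {
  set.seed(seed)
  data.frame(r_in = runif(n, -5, 10), t_in = runif(n, 0.1, 10),
             r_out = runif(n, -5, 10), t_out = runif(n, 0.1, 10))
}

# random SS/LL choice instance with t_ss < t_ll
random_choice <- function(seed) {
  set.seed(seed)
  t_ss <- runif(1, 0.2, 5)
  list(ss = pursuit(runif(1, 0.1, 5), t_ss),
       ll = pursuit(runif(1, 0.1, 10), t_ss + runif(1, 0.2, 10)),
       o = outside_context(runif(1, -2, 8), runif(1, 0.5, 10)))
}
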
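---
title: "Valuing the initiation of a pursuit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing the initiation of a pursuit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitvalue)
```

## The model

`pursuitvalue` analyses temporal decision-making worlds built from
*pursuits*: paths that consume a fixed time `t` and deliver a reward `r`
(any sign), after which the agent re-enters the rest of the world. Worlds
are recurrent: under any policy the agent eventually returns to where it
started, so every policy has a well-defined long-run *global reward rate*
`rho_g`, and a normative agent picks the policy maximising it.

Two primitive decisions about initiating a pursuit are covered:

* **Forgo** — accept or reject a single offered pursuit, returning to a
  default pursuit (a waiting state, possibly rewarded at rate `rho_d`)
  either way;
* **Choice** — select one of two mutually exclusive pursuits, conventionally
  a smaller-sooner (SS) versus a larger-later (LL) reward.

In a forgo world with pursuits encountered from the default pursuit at
frequencies `f_i` (Poisson rates per unit default time), the global rate of
a policy accepting the set `A` is

```
rho_g = (sum_{i in A} f_i r_i + rho_d) / (sum_{i in A} f_i t_i + 1)
```

— one unit of default time per normalisation cycle in the denominator,
which is exactly the expectation of the renewal process that
`simulate_traversals()` implements. The world can equivalently be
parcelled, from the perspective of one accepted pursuit type, into the time
spent *inside* it (`t_in`, reward `r_in`) and everything *outside* it per
traversal (`t_out`, reward `r_out`), giving

```
rho_g = (r_in + r_out) / (t_in + t_out)
      = w_in * rho_in + (1 - w_in) * rho_out,   w_in = t_in / (t_in + t_out)
```

`parcel_world()` performs the reduction and the package's property tests
assert the identity on randomly generated worlds.

## Subjective value and the two components of time's cost

The worth of initiating a pursuit is expressed as its *subjective value*
(sv): the immediate reward an optimal agent would accept in place of the
pursuit. Two algebraically equivalent forms are implemented:

```
sv = r_in - rho_g * t_in                                  (global-rate form)
sv = (r_in - rho_out * t_in) * t_out / (t_in + t_out)     (in/outside form)
```

The in/outside form exposes the structure of time's cost
`rho_g * t_in`:

* **opportunity cost** `rho_out * t_in` — reward expected from *not* taking
  the pursuit over its duration;
* **apportionment cost** `t_in * (rho_g - rho_out)` — the remainder, driven
  by the fraction of time the pursuit occupies. It is computed in this
  compact form for numerical stability; the expanded occupancy-weighted
  form `t_in * (rho_in - rho_out) * w_in` is asserted equal in the tests.

```{r}
vb <- subjective_value_in_out(pursuit(4, 4), outside_context(0.7, 3))
vb
```

Sign conventions fall out of the algebra: `sv > 0` exactly when
`rho_in > rho_out`, so the forgo rule "take iff the pursuit's local rate
beats its outside rate" and the rule "take iff sv > 0" coincide. A pursuit
of zero duration is legal and is worth its reward in every form, since sv
is by definition an immediate-reward equivalent.

## Policies, thresholds and the region map

`choice_decision()` compares the global rates of the two single-pursuit
policies sharing an outside. It is equivalent to the marginal-rate rule
(choose LL iff `(r_LL - r_SS) / (t_LL - t_SS)` exceeds the attained rate)
and to comparing subjective values; the equivalence is property-tested on
random instances rather than assumed.

As the outside reward rate rises with the outside time fixed, the optimal
behavior triplet (choice, forgo-LL, forgo-SS) passes through a fixed
sequence of regions whenever the SS pursuit has the higher local rate and
an LL-first region exists:

```{r}
ss <- pursuit(2.5, 2.5); ll <- pursuit(5, 8.5)
sapply(c(0, 0.4, 0.8, 1.3), function(rho)
  format(behavior_triplet(ss, ll, outside_context(rho * 6, 6))))
```

`critical_outside_rate_for_choice()` returns the first boundary in closed
form (a linear equation in the rate); `critical_outside_time_for_choice()`
brackets and bisects the sv difference in the outside time (tolerance
1e-10), since the closed form is less transparent there.
`policy_region_map()` sweeps a rate grid (optionally crossed with an error
magnitude `omega`, below) and refines each region boundary by bisection to
~1e-18 of the grid interval.

`optimal_accept_set()` implements the iterative pruning policy for n-pursuit
forgo worlds: repeatedly drop any accepted pursuit whose local rate falls
below its current outside rate, lowest-rate violator first with ties broken
by index (a deterministic order; the fixed point is order-independent). The
exhaustive `brute_force_optimal_accept_set()` — capped at 20 pursuits, with
ties broken toward the smaller then lexicographically earlier subset — is
kept as an independent oracle and the two are compared on random worlds.

## The apparent discounting function

Normalising the sv-by-delay function by the outcome magnitude gives the
apparent discounting function of a reward-rate-optimal agent,

```
D(t) = (1 - rho_out * t / r) / (1 + t / t_out)
```

a hyperbola whose curvature is set by `1 / t_out` (apportionment) with a
linear numerator correction set by `rho_out` (opportunity cost). The delay
is modelled as the pursuit's full duration; there is no separate
pre-/post-reward split. With `rho_out = 0` the curve is exactly
`1 / (1 + t / t_out)` and `fit_hyperbolic_k()` recovers `k = 1 / t_out` to
1e-6; with `rho_out > 0` the fitted `k` is inflated because the standard
hyperbola has no opportunity-cost term. The fit is unweighted least squares
on the value scale over the supplied delay grid (default 41 points on
`[0, 4 t_out]`); no fitting protocol is canonical here, so the simplest one
is used and documented. Negative discount values are reported as-is — they
mark delays at which the pursuit should be forgone when possible.

Three classic phenomena follow from the same expression and are exposed as
constructions: the **Magnitude effect** (`magnitude_effect_curves()`;
larger rewards discount more shallowly, vanishing at `rho_out = 0`), the
**Sign effect** (`sign_effect_curves()`; punishments discount more
shallowly, vanishing at `rho_out = 0` and inverting for `rho_out < 0`), and
the **Delay effect** (`preference_reversal_delay()`; preference reverses
from SS to LL as a common delay grows). Steepness orderings are asserted
pointwise on delay grids — the effects have no canonical scalar "steepness"
summary, and pointwise dominance is the stronger claim.

## Misestimation and the malapportionment agent

`misestimation_spec()` defines six error models, each multiplying one
ingredient of the perceived global rate by `omega`: outside time, outside
reward, inside time, inside reward, or a side's reward *and* time together
(which preserves that side's perceived reward rate). Decision rules for a
misestimating agent mirror the optimal architecture with perceived
quantities substituted: choices compare perceived global rates, forgo
decisions compare perceived local against perceived outside rates.

The single-variable errors that produce impatient choice necessarily
distort a forgo threshold, because they distort a perceived rate. Only the
rate-preserving misweightings leave both forgo thresholds exactly optimal
while still shifting the choice threshold toward SS — underweighting the
outside (`omega < 1`) and overweighting the inside (`omega > 1`) are the
same agent up to reparameterisation, and both are exposed. This is the
*malapportionment* agent; `malapportionment_curves()` bundles its four
signatures (steeper discounting, attenuated Magnitude and Sign effects, a
deferred preference reversal).

```{r}
mp <- malapportionment_curves(pursuit(2, 3), pursuit(5, 12.6),
                              outside_context(2.5, 5), omega = 0.5,
                              sign_magnitude = 3)
mp$reversal
```

### Where the added delay lives

One modelling question is genuinely open in the Delay-effect construction:
when a common delay `d` is prepended to both choice options, is it part of
each pursuit or part of the world outside them? For a veridical agent the
question is moot — the policy rates are `(r + r_out) / (t + d + t_out)`
either way. For a misweighting agent it matters. This package treats the
common delay as lying on the path shared by both policies, i.e. *outside*
either considered pursuit: a segment common to every policy cannot
discriminate between them and belongs to the context, and choice worlds are
defined here by options presented after a shared period. The
malapportionment agent therefore underweights the added delay along with
the rest of the outside, and its perceived reversal delay is
`d_hat = u / omega - t_out` with
`u = (A t_LL - B t_SS) / (B - A)`, `A = r_SS + omega r_out`,
`B = r_LL + omega r_out` — strictly larger than the optimal delay for
`omega < 1` and growing as the underweighting deepens, a more pronounced
Delay effect alongside the attenuated Magnitude and Sign effects. Under the
alternative reading (delay folded into each pursuit's duration) the same
agent would reverse *earlier* than optimal, which would make the deferred
reversal unobtainable in principle; the shared-path reading is the one
consistent with the rest of the malapportionment phenomenology.

## Numerical choices

* Rate comparisons use an absolute indifference band, `tol = 1e-9` by
  default: equality cases are meaningful in this algebra (they mark policy
  equivalence), and floats need a band to land on them.
* Breakdown identities (opportunity + apportionment = time cost; the two sv
  forms) are tested to 1e-9 absolute / 1e-10 relative.
* Root finding: sv crossings are bracketed on a 200-point logarithmic grid
  and refined with `uniroot` at tolerance 1e-12; a curve that is zero
  everywhere (identical pursuits) is reported as having no crossing rather
  than an arbitrary root.
* The `k` fit uses `optimize` on `[0, max(1, 100 / min positive delay)]`
  with tolerance 1e-12 and an explicit check of the `k = 0` corner.
* Simulation waiting times are exponential — the memoryless reading of
  "encountered at frequency f" — and opportunities arriving while the agent
  is engaged are discarded, not queued. Standard errors use batch means
  over 100 consecutive batches, which respects the renewal correlation
  structure that a naive per-encounter variance would ignore.

## What the random-world generator does and does not emulate

`generate_random_world()` draws durations on (0.1, 10), rewards on (-5, 10)
(negative outcomes included, as the Sign-effect analysis requires),
encounter frequencies on (0.05, 2) and default rates on (0, 1). These
ranges put local and outside rates on comparable scales so that accept-set
pruning, sign rules and the rate identities are exercised across both
orderings of `rho_in` versus `rho_out`. The generator emulates the
*structure* of recurrent pursuit worlds, not empirical task statistics: it
has no learning or estimation noise, no within-pursuit dynamics, no
non-stationarity, and pursuit parameters are mutually independent. Tests
passing on these worlds therefore establish the algebraic and policy
properties of the implementation, not behavioral realism of any particular
experiment.

Problem sizes used by the test suite were chosen to make the checks sharp
yet quick: 1e4 random parameter draws for the sv-equivalence identity, 200
random worlds of up to 12 pursuits for the pruning-versus-enumeration
comparison, and 20 random worlds simulated for 1e5 encounters each (a 3
standard-error criterion, with a single reseed allowed since a 3-sigma test
alone is expected to fail about once in 370 draws).

## Known limitations

* Worlds must be recurrent; absorbing states are out of scope.
* Pursuits are atomic: no patch-residence, give-up times or partial
  abandonment — only initiate-or-not decisions.
* Encounter frequencies may be arbitrarily high; no saturation of the
  default pursuit is modelled.
* `fit_hyperbolic_k()` fits the standard single-parameter hyperbola only;
  no exponential or quasi-hyperbolic model zoo, and no fitting of empirical
  choice data or of `omega` to datasets.
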
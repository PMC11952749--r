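# pursuitvalue

How much is it worth to *start* something? `pursuitvalue` implements a
normative account of that question for temporal decision-making worlds
built from **pursuits** — paths that consume a time `t_in` and return a
reward `r_in` (possibly negative) before the agent re-enters the rest of
the world. It is aimed at computational neuroscientists, behavioral
ecologists and economists who want executable, tested versions of
reward-rate-maximising valuation, policy and discounting calculations, and
of the misestimation analyses used to interpret how real agents deviate
from them.

## The core quantities

For a recurrent world parcelled into a considered pursuit and everything
outside it (time `t_out`, reward `r_out` per traversal, rate
`ρ_out = r_out / t_out`), the global reward rate under a policy of
accepting the pursuit is

    ρ_g = (r_in + r_out) / (t_in + t_out)

and the pursuit's **subjective value** — the immediate reward an optimal
agent would treat as equivalent to initiating it — has two equivalent
forms:

    sv = r_in − ρ_g t_in = (r_in − ρ_out t_in) · t_out / (t_in + t_out)

Time's cost `ρ_g t_in` splits into an **opportunity cost** `ρ_out t_in`
and an **apportionment cost** `t_in (ρ_g − ρ_out)`. From these the package
derives reward-rate-optimal Forgo (take iff `ρ_in > ρ_out`) and Choice
policies, the apparent discounting function

    D(t) = (1 − ρ_out t / r) / (1 + t / t_out)

(purely hyperbolic with `k = 1/t_out` when `ρ_out = 0`), the Magnitude,
Sign and Delay effects, and a six-model family of parameter-misestimating
agents — including the *malapportionment* agent, which misweights time
outside versus inside a pursuit while preserving both reward rates, and so
chooses impatiently while still forgoing optimally.

## Worked example

A pursuit worth 4 reward units after 4 time units, embedded in an outside
yielding 0.7 reward units over 3 time units:

```r
library(pursuitvalue)
subjective_value_in_out(pursuit(4, 4), outside_context(0.7, 3))
#> <valuation_breakdown>
#>   subjective value   : 1.31429
#>   global reward rate : 0.671429
#>   occupancy weight   : 0.571429
#>   time cost          : 2.68571
#>     opportunity cost : 0.933333
#>     apportionment    : 1.75238
```

The pursuit's local rate (1) beats its outside rate (0.233), so the sv is
positive: accepting it raises the global rate from 0.233 to 0.671, and an
immediate reward of 1.314 would do exactly as well. Of the 2.686 time
cost, 0.933 is reward forgone elsewhere (opportunity) and 1.752 comes from
the pursuit occupying 4/7 of each traversal (apportionment).

Sweeping the outside rate for a smaller-sooner (2.5 after 2.5) versus
larger-later (5 after 8.5) pair with 6 time units outside reproduces the
canonical policy transitions:

```r
ss <- pursuit(2.5, 2.5); ll <- pursuit(5, 8.5)
sapply(c(0, 0.4, 0.8, 1.3), function(rho)
  format(behavior_triplet(ss, ll, outside_context(rho * 6, 6))))
#> [1] "LL/take/take"   "SS/take/take"   "SS/forgo/take"  "SS/forgo/forgo"
```

and the malapportionment agent (`omega = 0.5`) keeps both forgo policies
optimal while deferring the Delay-effect preference reversal:

```r
malapportionment_curves(pursuit(2, 3), pursuit(5, 12.6),
                        outside_context(2.5, 5), omega = 0.5,
                        sign_magnitude = 3)$reversal
#> $optimal
#> [1] 6.4
#>
#> $perceived
#> [1] 9.8
```

## Command-line interface

A thin Rscript over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pursuitvalue.R", package = "pursuitvalue"))')
Rscript $CLI value --spec inst/extdata/demo-pursuit.json
Rscript $CLI regions --spec inst/extdata/demo-choice.json --rates 0,1.3,0.01 --out regions.csv
Rscript $CLI simulate --spec inst/extdata/demo-forgo-world.json --n 100000 --seed 1
```

Subcommands: `value`, `forgo`, `choose`, `regions`, `discount`,
`misestimate`, `simulate`; world specifications are JSON or YAML (see
`?load_world_spec` for the schema). Sweeps are written as long-format CSV
with a header row.

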
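Package: pursuitvalue
Title: Reward-Rate-Optimal Valuation of Initiating Pursuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for normative analysis of temporal decision-making worlds
    composed of recurrent pursuits. Computes the global reward rate attained
    under accept/forgo policies, the subjective value of initiating a pursuit
    and its decomposition of time's cost into opportunity and apportionment
    costs, reward-rate-optimal Forgo and Choice policies with their critical
    thresholds and policy-region maps, the apparent temporal discounting
    function of a reward-rate-maximizing agent (including Magnitude, Sign and
    Delay effect constructions and standard hyperbolic k fitting), and a
    family of parameter-misestimation agents including the malapportionment
    agent that underweights time spent outside a pursuit while preserving
    reward rates. Includes stochastic traversal simulation and exhaustive
    policy enumeration as independent cross-checks, world-specification file
    I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
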
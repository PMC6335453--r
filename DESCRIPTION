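Package: knapbayes
Title: Instance Complexity of the 0-1 Knapsack Problem and Sampling-Based Belief Updating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying decision-making under complexity-driven
    uncertainty. Provides exact solvers (exhaustive, dynamic programming,
    branch-and-bound) for the 0-1 knapsack problem, the Sahni-k instance
    complexity metric, enumeration of maximal feasible (capacity-filled)
    item subsets, exact big-integer counting of weak orders (total
    preorders) and state spaces, and seeded simulations contrasting
    Bayesian belief updating from informative binary signals with
    sampling-based belief updating driven by randomly assembled knapsacks.
    Includes parameterized generators for random knapsack instances and
    Bernoulli signal streams, CSV/JSON reporting, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
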
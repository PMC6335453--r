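---
title: "Complexity-driven uncertainty: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity-driven uncertainty: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knapbayes)
```

## The problem

A decision-maker choosing among subsets of goods faces two very different
kinds of ignorance. When payoffs are genuinely random, probability theory
is the right language: beliefs are probabilities, evidence accumulates
through Bayes' Law, and sampling reduces uncertainty at a geometric rate.
But when the unknown is the *solution of a hard computation* — which
items belong in an optimal knapsack — probabilistic sampling can be a
poor tool: the uncertainty is not stochastic, and random trial-and-error
explores a combinatorial space with no gradient toward the answer.

This package implements both regimes side by side on a common test bed,
the 0–1 knapsack problem, together with the exact combinatorial counts
that quantify what "complete preferences" would cost, and a per-instance
complexity metric (Sahni-k) that predicts how hard a given instance is.

## The knapsack test bed

The canonical instance (`fixture_backpacking()`) has ten items with
values (31, 141, 46, 30, 74, 105, 119, 160, 59, 71), weights
(21, 97, 32, 21, 52, 75, 86, 116, 43, 54) and capacity 265. Its relevant
structure:

* value-to-weight densities are nearly constant (1.31–1.48), which is
  exactly the regime where greedy heuristics fail;
* the unique optimum is items {2, 5, 8} with value 375 and weight
  exactly 265 (zero slack);
* greedy from the empty seed returns items 1–5 with value 322;
* the Sahni-k complexity is 3;
* there are 82 *capacity-filled* knapsacks.

```{r fixture}
inst <- fixture_backpacking()
solve_dp(inst)
sahni_k(inst)
length(enumerate_maximal(inst))
```

### Exact solvers

`solve_bruteforce()` enumerates all `2^n` subsets by iterative doubling
and is the oracle the others are tested against (refused above 25 items).
`solve_dp()` fills the standard weight-indexed table in `O(n * capacity)`
with an exact count of optima per cell, so its uniqueness flag needs no
second pass; ties in the traceback are resolved by preferring to exclude
higher-indexed items, making the returned selection deterministic.
`solve_branch_and_bound()` searches in decreasing-density order with the
fractional-relaxation bound, and certifies uniqueness by a second,
bounded counting pass that stops as soon as two optima are seen. All
three agree on 200 random instances in the test suite.

### The capacity-filled reading

"Capacity-filled" is implemented as *maximal feasible*: a feasible subset
to which no excluded item can be added without overflowing. This is the
only reading under which the collection is finite and enumerable — and
it is also precisely the set of possible outcomes of any procedure that
keeps adding items until nothing fits, which is what makes `1/82` the
per-trial success probability of uniform random search on this instance.
Exact-fill (weight equal to capacity) would be a different and much
smaller set, and greedy-reachable sets a different one again; both
alternatives are ruled out because the uniform-sampling arithmetic below
requires the maximal-feasible space.

### Sahni-k

`sahni_candidate(inst, k)` completes every feasible seed of **at most**
`k` items with the greedy rule and keeps the best completion. The
cumulative ("at most") seeding is deliberate: it makes the candidate
value non-decreasing in `k` and guarantees the optimum is reached at
`k = n`, the two properties that make "smallest sufficient `k`" a
well-defined complexity metric. (Seeding with *exactly* `k` items — also
available via `seed_cardinality = "exactly_k"` — loses both properties:
on the fixture the exactly-4 candidate is worth only 372 because no
4-item superset of the zero-slack optimum is feasible.) Density ties are
broken by lower item index and value ties by the lexicographically
smallest selection, so the procedure is fully deterministic. The greedy
scan continues past items that do not fit; the stricter
stop-at-first-misfit variant is kept behind a flag for sensitivity
analysis, since with near-constant densities the first misfit usually
occurs late and the two variants often coincide.

## Counting what completeness demands

For a chooser over `n` goods, completeness of preferences means holding a
ranking-with-ties (a weak order, i.e. a total preorder) over all
`2^n` subsets. The number of weak orders on `n` alternatives is the
ordered Bell number `sum_k k! * S(n, k)`; for `n = 10` this is
102 247 563. Ten binary securities over 30 periods span
`2^300` joint payoff states.

```{r counts}
combinatorics_report(10, 30)
```

These counts must be exact — `2^300` has 91 digits — so the package
carries a minimal nonnegative big-integer type (`bignat`): base-10^6
limbs stored in doubles, schoolbook addition and multiplication, with
every intermediate product (< 10^12 per limb pair) far inside the
exactly-representable double range. The test suite cross-checks it
against double arithmetic below 2^53, against frozen decimal strings for
20! and 2^300, against a brute-force enumeration of all total preorders
for n ≤ 4, and against the Bell numbers via the independent triangle
recurrence.

## The two learning regimes

### Probabilistic uncertainty (securities)

Ten securities each pay 1 or 0; the payoff vector of the worked example
is (0,0,0,0,0,0,0,1,1,1). Each trial delivers one conditionally
independent binary signal per security that matches its payoff with
probability `q = 0.7`. Beliefs start at the symmetric prior 0.5 and are
updated by Bayes' Law; the posterior depends on the signal history only
through the count difference, via the likelihood-ratio closed form
implemented in `bayes_closed_form()` (an identity the tests verify
exhaustively for all signal sequences up to length 8). Signals are
independent across securities and trials; beliefs at 0 or 1 are
absorbing. With `q = 0.7` and 30 trials, the probability that a
security's majority signal points the right way is about 0.983, so
beliefs almost always converge to the payoffs — the mean absolute belief
error at trial 30 is about 0.016 in the test suite.

### Complexity-driven uncertainty (backpacking)

The sampling-based learner holds one belief per item that it is in the
optimal knapsack, again starting at 0.5. Each trial draws a random
capacity-filled knapsack, compares its value with the incumbent
best-so-far, emits a binary membership signal per item — from the new
sample if it strictly improved, from the incumbent otherwise — and
updates each belief by weighting the previous belief by `(t-1)/t` and
the signal by `1/t`, i.e. beliefs are running means of the emitted
signals. This updating uses a *misspecified* likelihood (the true
likelihood of a sampled value given the optimum is unknowable without
solving the problem), which is permitted: only coherence, not
correctness, of the prior is assumed.

Two under-specified corners are resolved as follows and recorded here as
package design choices:

* **Trial 1:** the incumbent starts at value `-Inf`, so the first sample
  always counts as an improvement and supplies the first signals. The
  prior's weight is `(t-1)/t = 0` at `t = 1`, so this choice only
  determines which selection emits the first signal.
* **Ties:** a sample whose value exactly equals the incumbent's is
  treated as *not* improved — signals come from the incumbent, which is
  retained. Only the strict comparisons are specified; treating ties as
  improvements would change nothing about values, only about which of
  two equal-valued selections emits signals.

Two sampling modes are provided because the narrative description
("randomly pick items until the weight limit is reached") and the
analytic arithmetic (each capacity-filled knapsack drawn with
probability 1/82) describe different processes:

* `"sequential-fill"` — items considered in uniformly random order, each
  added if it fits, all items considered. The result is always maximal,
  but not uniform: the zero-slack optimum {2,5,8} is drawn only when
  items 2, 5, 8 come up first in some order, probability
  `3!/(10*9*8) = 6/720`, below 1/82. This is the default for trajectory
  reproduction.
* `"uniform-maximal"` — a uniform draw from the 82 enumerated maximal
  sets. All closed-form claims (per-trial probability `1/82`, discovery
  probability `1 - (81/82)^30 ≈ 0.308`, trials to 95% confidence) are
  computed and tested under this mode.

The closed forms expose an inconsistency worth flagging: with per-trial
probability 1/82, the 30-trial discovery probability is ≈ 31% (not a
few percent), and 95% confidence needs 245 trials; under the
sequential-fill probability 6/720 the figures are ≈ 22% and 358 trials.
Either way the qualitative conclusion stands — random sampling needs
several times more steps than the 82-step exhaustive listing. The
package reports the closed forms as computed; nothing is tuned to match
any other figure. A related arithmetic detail: the minimal `T` with
`1 - (81/82)^T >= 0.95` is 245, since coverage at `T = 244` is 0.94991,
just under target; `trials_for_confidence()` therefore returns 245 (and
the neighbouring-integer check in the implementation guards the ceiling
against floating-point edge effects).

```{r closedforms}
discovery_probability(1 / 82, 30)
trials_for_confidence(1 / 82, 0.95)
trials_for_confidence(6 / 720, 0.95)
```

### The contrast, stated testably

Run both regimes for 30 trials: the Bayesian learner's mean absolute
belief error (against the payoffs) ends below 0.15, while the sampling
learner's (against the optimum's membership indicator) stays above 0.25.
The test suite checks both bounds over 1,000 seeded runs each; typical
values are ≈ 0.016 and ≈ 0.42. The deeper reason for the failure is that
running-mean beliefs track *membership frequency among good-so-far
samples*, which for near-constant-density instances is only weakly
related to membership in the optimum — and the signals carry no
likelihood information at all.

## Randomness and reproducibility

Every stochastic routine takes a single integer seed
(`sampler_config(seed = ...)`, `instance_gen_spec(seed = ...)`) and
consumes one R random stream in a documented order (within a trial,
per-unit draws in unit order). Seeded runs are bit-reproducible on a
given platform; the RNG state of the caller is saved and restored, so
package calls do not perturb user-level randomness. Trajectory CSVs
print floating point at 12 significant digits, making reruns with equal
seeds byte-identical.

## The synthetic instance generator

`generate_instance()` emulates the fixture's structure: integer weights
uniform on a range (default 20–120, the fixture's span), values
`round(weight * density)` with density uniform in `1.4 ± 0.1` (the
fixture's densities span 1.31–1.48), and capacity a fraction of total
weight (default 0.44 ≈ 265/597). This strongly correlated family is the
regime where greedy fails and Sahni-k is informative; raising
`density_jitter` moves toward easier, uncorrelated instances. The
generated optima are tight — in ≥ 95% of seeds the optimum fills ≥ 90%
of capacity — which the test suite verifies with the exact solver over
200 seeds. What the generator does **not** emulate: real experimental
instance banks stratified by human difficulty, non-integer data, or
correlated signal noise; conclusions from passing tests are claims about
this instance family, not about human task batteries.

## Problem sizes used in the test suite

Solver-agreement properties run on 200 random instances of 3–12 items
(brute force is exact and fast there); maximality enumeration is
cross-checked against a direct subset filter at 7 items; the
uniform-sampling uniformity check uses 50,000 draws; the Monte-Carlo
discovery check uses 10,000 runs of 30 trials; the regime-contrast check
uses 1,000 seeded runs per regime. These sizes give Monte-Carlo standard
errors comfortably below the margins being tested (all stochastic checks
use 3-standard-error bands) while keeping the whole suite around a
minute of CPU.

## Known limitations

* Exhaustive enumeration guards are deliberate (25 items for brute
  force, 20 for maximal-set enumeration); beyond them the solvers refuse
  rather than silently approximate. No FPTAS or approximation scheme is
  provided.
* The Sahni-k computation is exponential in k by construction; it is a
  complexity *metric*, not a practical solver.
* `bignat` implements only what exact counting needs (nonnegative
  add/multiply/power/compare); it is not a general bignum library —
  no subtraction, division or negative numbers.
* The sampling-regime learner is the specified misspecified-likelihood
  procedure; no ideal-observer baseline for that regime is implemented,
  and no human-strategy (branch-and-bound-like) simulation beyond the
  exact solver is attempted.
* Weak-order *enumeration* (as opposed to counting) is only done up to
  n = 4, inside the test oracle.
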
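# knapbayes

Tools for studying decision-making when uncertainty comes not from
randomness but from the **computational complexity** of the decision
problem itself.

Classical decision theory represents all uncertainty with probabilities:
beliefs are updated by Bayes' Law, and sampling steadily reduces
uncertainty. That picture works when payoffs really are random — but many
everyday choices (packing, budgeting, portfolio selection) are instances
of hard combinatorial optimization problems such as the 0–1 knapsack
problem, where the decision-maker's ignorance is about the *solution of a
computation*, not a coin flip. `knapbayes` provides the machinery to make
that contrast quantitative, for researchers in computational cognitive
science, decision theory and behavioural economics.

## What it computes

**Knapsack core.** For an instance with values *v*, weights *w* and
capacity *c*, the task is max Σᵢ vᵢxᵢ s.t. Σᵢ wᵢxᵢ ≤ c, xᵢ ∈ {0,1}.
Three exact solvers (`solve_bruteforce`, `solve_dp`,
`solve_branch_and_bound`) share one result contract (optimal value, an
attaining selection, a uniqueness flag). `enumerate_maximal` lists every
*capacity-filled* knapsack — a feasible subset to which no excluded item
can be added — the finite sample space of random trial-and-error search.

**Sahni-k instance complexity.** `greedy_fill` completes a seed subset by
scanning items in decreasing value-to-weight order; `sahni_candidate(x, k)`
takes the best greedy completion over all feasible seeds of up to `k`
items; `sahni_k` is the smallest `k` whose candidate attains the true
optimum. `k = 0` means plain greedy suffices; larger `k` means the
instance needs more exhaustive search, making Sahni-k a per-instance
measure of computational difficulty.

**Preference combinatorics.** Exact big-integer counts of what preference
completeness demands: `subset_count(n) = 2^n` choice sets,
`weak_order_count(n) = Σₖ k!·S(n,k)` complete rankings-with-ties (S = Stirling
numbers of the second kind), and `state_space_size(units, periods) =
2^(units·periods)` joint payoff states. All arithmetic is exact at any
size (2^300 never touches floating point).

**Belief dynamics.** `simulate_securities_learning` runs Bayesian updating
of beliefs about 10 binary securities from conditionally independent
signals of accuracy *q* (posterior odds multiply by *q*/(1−*q*) per
positive signal). `simulate_sampling_learning` runs the sampling-based
learner: draw a random capacity-filled knapsack, compare it with the
incumbent best, emit membership signals from whichever is better, and
update each belief as the running mean of its signals.
`discovery_probability(p, T) = 1 − (1−p)^T` and `trials_for_confidence`
give the closed-form arithmetic of random search.

## Worked example

```r
library(knapbayes)

inst <- fixture_backpacking()   # 10 items, capacity 265
solve_dp(inst)
#> optimal value 375 via dp; items {2,5,8} (unique optimum)

sahni_k(inst)                   # 3: greedy + seeds of <= 2 items all fail
#> [1] 3

length(enumerate_maximal(inst)) # capacity-filled knapsacks
#> [1] 82

discovery_probability(1/82, 30) # chance random search finds the optimum in 30 trials
#> [1] 0.3079539
trials_for_confidence(1/82, 0.95)
#> [1] 245
```

So even though only 82 candidate stopping points exist — a brute-force
list-and-pick needs just 82 steps — uniform random sampling finds the
best one within 30 trials only ~31% of the time and needs 245 trials for
95% confidence.

The two learning regimes, same trial budget, same seed:

```r
tr <- simulate_securities_learning(fixture_securities_payoffs(),
                                   sampler_config(trials = 30, seed = 1))
round(tr$beliefs[30, ], 3)
#>  [1] 0.000 0.000 0.000 0.000 0.006 0.000 0.000 1.000 1.000 0.994

tr2 <- simulate_sampling_learning(inst, sampler_config("sequential-fill",
                                                       trials = 30, seed = 1))
round(tr2$beliefs[30, ], 3)
#>  [1] 1.000 0.000 1.000 0.833 0.200 0.800 0.033 0.967 0.200 0.000
tr2$found_optimum
#> [1] FALSE
```

After 30 trials the Bayesian learner has essentially identified the
paying securities (8, 9, 10), while the sampling-based learner's beliefs
bear little relation to the optimal items {2, 5, 8} and the optimum was
never even sampled.

Preference-completeness counts for 10 goods over 30 periods:

```r
combinatorics_report(10, 30)
#> $n: 10        $subsets: 1024        $weak_orders: 102247563
#> $states_per_period: 1024
#> $states_total: "2037035976334486086268445688409378161051468393665936250636140449354381299763336706183397376"
```

## Command line

```sh
Rscript inst/cli/knapbayes.R solve --instance inst/extdata/backpacking_instance.txt
Rscript inst/cli/knapbayes.R combinatorics --n 10 --periods 30
Rscript inst/cli/knapbayes.R compare-regimes --outdir out/ --seed 1
```

Subcommands: `solve`, `sahni-k`, `enumerate-maximal`, `combinatorics`,
`simulate-securities`, `simulate-sampling`, `compare-regimes`,
`generate-instance`, `fixtures`. See `?run_analysis`.

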
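fixture <- fixture_backpacking()

test_that("instance and selection constructors enforce their invariants", {
  expect_error(knapsack_instance(c(1, 2), c(3), 5), "equal, nonzero length")
  expect_error(knapsack_instance(c(0, 2), c(3, 4), 5), "positive integers")
  expect_error(knapsack_instance(c(1, 2), c(3, 4), -1), "nonnegative")
  expect_error(item_selection(fixture, c(1, 1)), "distinct")
  expect_error(item_selection(fixture, 11), "out of range")
  sel <- item_selection(fixture, c(8, 2, 5))
  expect_identical(sel$indices, c(2L, 5L, 8L))
  expect_equal(sel$total_value, 375)
  expect_equal(sel$total_weight, 265)
})

test_that("feasibility and maximality match direct arithmetic on the fixture", {
  expect_true(is_feasible(fixture, c(2, 5, 8)))    # weight 265 = capacity
  expect_true(is_feasible(fixture, integer(0)))
  expect_false(is_feasible(fixture, c(1, 2, 5, 8)))
  expect_true(is_maximal(fixture, c(2, 5, 8)))     # zero slack
  expect_false(is_maximal(fixture, integer(0)))    # every single item fits
  expect_true(is_maximal(fixture, 1:5))            # slack 42 < min excluded weight 43
  expect_error(is_maximal(fixture, c(1, 2, 5, 8)), "infeasible")
})

test_that("all three exact solvers find the fixture's unique optimum {2,5,8}", {
  for (solver in list(solve_bruteforce, solve_dp, solve_branch_and_bound)) {
    res <- solver(fixture)
    expect_equal(res$optimal_value, 375)
    expect_identical(res$optimal_selection$indices, c(2L, 5L, 8L))
    expect_true(res$is_unique)
    expect_true(is_feasible(fixture, res$optimal_selection))
  }
})

test_that("solvers handle degenerate instances", {
  one <- knapsack_instance(7, 3, 10)
  expect_equal(solve_bruteforce(one)$optimal_selection$indices, 1L)
  zero_cap <- knapsack_instance(c(5, 6), c(2, 3), 0)
  expect_equal(solve_dp(zero_cap)$optimal_value, 0)
  expect_length(solve_dp(zero_cap)$optimal_selection$indices, 0)
  expect_equal(solve_branch_and_bound(zero_cap)$optimal_value, 0)
  nothing_fits <- knapsack_instance(c(5, 6), c(20, 30), 10)
  expect_equal(solve_dp(nothing_fits)$optimal_value, 0)
  expect_length(solve_dp(nothing_fits)$optimal_selection$indices, 0)
})

test_that("solvers detect non-unique optima", {
  tie <- knapsack_instance(c(10, 10), c(5, 5), 5)  # either item alone
  for (solver in list(solve_bruteforce, solve_dp, solve_branch_and_bound)) {
    res <- solver(tie)
    expect_equal(res$optimal_value, 10)
    expect_false(res$is_unique)
  }
})

test_that("size guards refuse oversized inputs with explicit errors", {
  big <- knapsack_instance(rep(1, 30), rep(1, 30), 10)
  expect_error(solve_bruteforce(big), "guard")
  expect_error(enumerate_maximal(big), "guard")
  wide <- knapsack_instance(1, 1, 1e9)
  expect_error(solve_dp(wide), "budget")
})

test_that("solvers agree with each other and an independent oracle on random instances", {
  for (seed in 1:40) {
    inst <- random_test_instance(n = sample(3:10, 1), seed = seed)
    bf <- solve_bruteforce(inst)
    expect_equal(solve_dp(inst)$optimal_value, bf$optimal_value)
    expect_equal(solve_branch_and_bound(inst)$optimal_value, bf$optimal_value)
    if (inst$n <= 8) expect_equal(bf$optimal_value, oracle_optimum(inst))
  }
})

test_that("greedy_fill follows the density order and respects seeds", {
  g <- greedy_fill(fixture, integer(0))
  expect_identical(g$indices, 1:5)
  expect_equal(g$total_value, 322)
  expect_equal(g$total_weight, 223)
  # a zero-slack seed cannot be extended
  expect_identical(greedy_fill(fixture, c(2, 5, 8))$indices, c(2L, 5L, 8L))
  expect_error(greedy_fill(fixture, c(1, 2, 5, 8)), "infeasible")
  one <- knapsack_instance(7, 3, 10)
  expect_identical(greedy_fill(one, integer(0))$indices, 1L)
  # the result is always maximal under the full-scan variant
  for (seed in 1:10) {
    inst <- random_test_instance(8, seed)
    expect_true(is_maximal(inst, greedy_fill(inst, integer(0))))
  }
})

test_that("Sahni candidates reproduce the fixture's value ladder", {
  expect_equal(sahni_candidate(fixture, 0)$optimal_value, 322)
  expect_equal(sahni_candidate(fixture, 1)$optimal_value, 367)
  expect_equal(sahni_candidate(fixture, 3)$optimal_value, 375)
  expect_equal(sahni_candidate(fixture, fixture$n)$optimal_value, 375)
  expect_error(sahni_candidate(fixture, 11), "k must be")
  expect_error(sahni_candidate(fixture, -1), "k must be")
})

test_that("Sahni candidate value is monotone in k and bounded by the optimum", {
  for (seed in c(3, 14, 27)) {
    inst <- random_test_instance(9, seed)
    opt <- solve_bruteforce(inst)$optimal_value
    vals <- vapply(0:inst$n,
                   function(k) sahni_candidate(inst, k)$optimal_value, numeric(1))
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals <= opt))
    expect_equal(vals[inst$n + 1], opt)
  }
})

test_that("sahni_k is minimal: the candidate at k-1 misses the optimum", {
  expect_equal(sahni_k(fixture), 3)
  for (seed in 1:15) {
    inst <- random_test_instance(sample(4:8, 1), seed)
    k <- sahni_k(inst)
    opt <- solve_bruteforce(inst)$optimal_value
    expect_lte(k, inst$n)
    expect_equal(sahni_candidate(inst, k)$optimal_value, opt)
    if (k > 0)
      expect_lt(sahni_candidate(inst, k - 1)$optimal_value, opt)
  }
})

test_that("greedy-alone-optimal instances have sahni_k zero", {
  inst <- knapsack_instance(c(60, 50, 1), c(10, 10, 10), 20)
  expect_equal(sahni_k(inst), 0)
})

test_that("enumerate_maximal returns exactly the maximal feasible subsets", {
  sels <- enumerate_maximal(fixture)
  expect_length(sels, 82)
  keys <- vapply(sels, function(s) paste(s$indices, collapse = ";"), character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_true("2;5;8" %in% keys)
  expect_true(all(vapply(sels, function(s) is_maximal(fixture, s), logical(1))))
  # lexicographic order of index sets
  expect_identical(keys, keys[order(vapply(sels, function(s)
    paste(sprintf("%04d", s$indices), collapse = " "), character(1)))])
  # cross-check against the independent subset filter on small instances
  for (seed in 1:8) {
    inst <- random_test_instance(7, seed)
    got <- lapply(enumerate_maximal(inst), function(s) s$indices)
    want <- oracle_maximal_sets(inst)
    key <- function(l) sort(vapply(l, paste, character(1), collapse = ";"))
    expect_identical(key(got), key(want))
  }
  # if everything fits, the only maximal set is the full set
  loose <- knapsack_instance(c(1, 2, 3), c(1, 1, 1), 10)
  all_sets <- enumerate_maximal(loose)
  expect_length(all_sets, 1)
  expect_identical(all_sets[[1]]$indices, 1:3)
})
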
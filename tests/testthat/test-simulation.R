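fixture <- fixture_backpacking()

test_that("sampler_config validates its fields", {
  cfg <- sampler_config("uniform-maximal", trials = 10, seed = 7, accuracy = 0.8)
  expect_s3_class(cfg, "sampler_config")
  expect_error(sampler_config(trials = 0), "positive integer")
  expect_error(sampler_config(accuracy = 0.5), "informative")
  expect_error(sampler_config("bogus"), "arg")
})

test_that("securities learning is seed-reproducible and perfect signals are decisive", {
  payoffs <- fixture_securities_payoffs()
  cfg <- sampler_config(trials = 30, seed = 5)
  a <- simulate_securities_learning(payoffs, cfg)
  b <- simulate_securities_learning(payoffs, cfg)
  expect_identical(a$beliefs, b$beliefs)
  expect_equal(dim(a$beliefs), c(30L, 10L))
  # q -> 1: one trial pins every belief to its payoff
  sure <- simulate_securities_learning(
    payoffs, sampler_config(trials = 1, seed = 1, accuracy = 1 - 1e-12))
  expect_equal(as.vector(sure$beliefs[1, ]), payoffs, tolerance = 1e-9)
})

test_that("securities trajectory endpoint equals the closed form on its signal counts", {
  payoffs <- fixture_securities_payoffs()
  for (seed in 1:5) {
    tr <- simulate_securities_learning(payoffs, sampler_config(trials = 8, seed = seed))
    for (j in 1:10) {
      n_pos <- sum(tr$signals[, j])
      expect_equal(tr$beliefs[8, j],
                   bayes_closed_form(0.5, n_pos, 8 - n_pos, 0.7),
                   tolerance = 1e-12)
    }
  }
})

test_that("beliefs mostly identify payoffs after 30 informative trials", {
  # majority of 30 accuracy-0.7 signals points the right way with
  # probability pbinom(14, 30, 0.3) ~ 0.983 per unit
  payoffs <- fixture_securities_payoffs()
  correct <- vapply(1:200, function(seed) {
    tr <- simulate_securities_learning(payoffs, sampler_config(trials = 30, seed = seed))
    mean(abs(tr$beliefs[30, ] - payoffs) < 0.5)
  }, numeric(1))
  expect_gt(mean(correct), 0.9)
})

test_that("both sampling modes return feasible, maximal selections", {
  msets <- enumerate_maximal(fixture)
  set.seed(2)
  for (i in 1:25) {
    s1 <- sample_knapsack_fill(fixture, "sequential-fill")
    s2 <- sample_knapsack_fill(fixture, "uniform-maximal", maximal_sets = msets)
    expect_true(is_maximal(fixture, s1))
    expect_true(is_maximal(fixture, s2))
  }
})

test_that("uniform-maximal draws are uniform over the 82 capacity-filled sets", {
  msets <- enumerate_maximal(fixture)
  M <- length(msets)
  n_draw <- 50000
  set.seed(31)
  idx <- vapply(seq_len(n_draw), function(i) {
    s <- sample_knapsack_fill(fixture, "uniform-maximal", maximal_sets = msets)
    match(paste(s$indices, collapse = ";"),
          vapply(msets, function(m) paste(m$indices, collapse = ";"), character(1)))
  }, numeric(1))
  freq <- tabulate(idx, nbins = M) / n_draw
  se <- sqrt((1 / M) * (1 - 1 / M) / n_draw)
  expect_true(all(abs(freq - 1 / M) <= 3 * se + 1e-12))
})

test_that("sequential-fill samples the optimum with probability 6/720", {
  # {2,5,8} fills the capacity exactly, so it is drawn iff the first three
  # draws are items 2, 5, 8 in some order: 3!/(10*9*8)
  p_exact <- 6 / (10 * 9 * 8)
  n_draw <- 30000
  set.seed(17)
  hits <- sum(vapply(seq_len(n_draw), function(i) {
    s <- sample_knapsack_fill(fixture, "sequential-fill")
    identical(s$indices, c(2L, 5L, 8L))
  }, logical(1)))
  se <- sqrt(p_exact * (1 - p_exact) / n_draw)
  expect_lt(abs(hits / n_draw - p_exact), 3 * se)
})

test_that("sampling-learning trajectories keep their accounting invariants", {
  for (mode in c("sequential-fill", "uniform-maximal")) {
    tr <- simulate_sampling_learning(fixture, sampler_config(mode, trials = 40, seed = 3))
    expect_equal(dim(tr$beliefs), c(40L, 10L))
    expect_true(all(diff(tr$incumbent_value) >= 0))
    expect_true(all(tr$beliefs >= 0 & tr$beliefs <= 1))
    # beliefs equal the running mean of the emitted signals: replay the
    # incumbent-comparison rule from the recorded samples
    inc_val <- -Inf; inc_sel <- integer(0); b <- rep(0.5, 10)
    for (t in seq_len(40)) {
      s <- tr$sampled_selections[[t]]
      improved <- s$total_value > inc_val
      if (improved) { inc_val <- s$total_value; inc_sel <- s$indices }
      b <- update_running_mean(b, make_signals(s, inc_sel, improved, 10), t)
      expect_equal(b, tr$beliefs[t, ], tolerance = 1e-14)
      expect_equal(inc_val, tr$incumbent_value[t])
    }
    # reruns with the same seed are identical
    tr2 <- simulate_sampling_learning(fixture, sampler_config(mode, trials = 40, seed = 3))
    expect_identical(tr$beliefs, tr2$beliefs)
    expect_identical(tr$incumbent_value, tr2$incumbent_value)
  }
})

test_that("first-hit bookkeeping marks runs that sample the optimum", {
  # with many trials under uniform-maximal, discovery is near-certain
  tr <- simulate_sampling_learning(fixture,
                                   sampler_config("uniform-maximal", trials = 600, seed = 8))
  expect_true(tr$found_optimum)
  expect_true(tr$first_hit_trial >= 1 && tr$first_hit_trial <= 600)
  expect_equal(tr$incumbent_value[tr$first_hit_trial], 375)
})

test_that("a first-trial optimum yields monotone convergence to its indicator", {
  # force the optimum first: seed chosen so the uniform draw is {2,5,8}?
  # instead, verify the algebra directly: running mean of a constant signal
  opt_sig <- make_signals(c(2, 5, 8), integer(0), TRUE, 10)
  b <- rep(0.5, 10)
  err <- numeric(5)
  for (t in 1:5) {
    b <- update_running_mean(b, opt_sig, t)
    err[t] <- mean(abs(b - opt_sig))
  }
  expect_equal(err, rep(0, 5))
})

test_that("trajectory export formats are stable and complete", {
  tr <- simulate_sampling_learning(fixture, sampler_config(trials = 5, seed = 1))
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 50)
  expect_named(df, c("trial", "unit", "belief", "incumbent_value", "sampled_selection"))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, p1)
  write_trajectory_csv(simulate_sampling_learning(fixture, sampler_config(trials = 5, seed = 1)), p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical reruns
  js <- tempfile(fileext = ".json")
  s <- run_summary(tr, js)
  expect_true(file.exists(js))
  got <- jsonlite::read_json(js)
  expect_equal(got$seed, 1)
  expect_equal(got$trials, 5)
  expect_length(got$final_beliefs, 10)
})
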
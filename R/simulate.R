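#' Configuration for a simulated learning run
#'
#' @param mode sampling mode for the knapsack regime: `"sequential-fill"`
#'   (draw not-yet-considered items uniformly, add each one that fits,
#'   until all have been considered) or `"uniform-maximal"` (draw uniformly
#'   from the set of all maximal feasible selections -- the model under
#'   which the per-trial discovery probability is exactly `1/M`).
#' @param trials positive integer trial budget (default 30).
#' @param seed integer seed; drives the single pseudo-random stream of the
#'   run and is recorded in every summary.
#' @param accuracy signal accuracy `q` in `(0.5, 1)` for the securities
#'   regime (default 0.7).
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(mode = c("sequential-fill", "uniform-maximal"),
                           trials = 30L, seed = 1L, accuracy = 0.7) {
  mode <- match.arg(mode)
  if (trials < 1 || trials != trunc(trials))
    stop("sampler_config: trials must be a positive integer")
  if (accuracy <= 0.5 || accuracy >= 1)
    stop("sampler_config: accuracy must lie in (0.5, 1) for informative signals")
  if (length(seed) != 1L || seed != trunc(seed))
    stop("sampler_config: seed must be a single integer")
  structure(list(mode = mode, trials = as.integer(trials),
                 seed = as.integer(seed), accuracy = accuracy),
            class = "sampler_config")
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  code
}

new_trajectory <- function(regime, beliefs, config, extra = list()) {
  structure(c(list(regime = regime, beliefs = beliefs,
                   trials = nrow(beliefs), n_units = ncol(beliefs),
                   mode = config$mode, seed = config$seed), extra),
            class = "belief_trajectory")
}

#' @export
print.belief_trajectory <- function(x, ...) {
  cat(sprintf("%s belief trajectory: %d trials x %d units (seed %d)\n",
              x$regime, x$trials, x$n_units, x$seed))
  cat("final beliefs:", paste(signif(x$beliefs[x$trials, ], 4), collapse = " "), "\n")
  if (!is.null(x$found_optimum))
    cat(sprintf("optimum sampled: %s (first hit trial: %s)\n",
                x$found_optimum, x$first_hit_trial))
  invisible(x)
}

#' Simulate Bayesian learning about binary securities
#'
#' The probabilistic-uncertainty regime: each of `length(payoffs)`
#' securities pays 1 or 0; in every trial the learner receives one
#' conditionally independent binary signal per security that matches its
#' payoff with probability `config$accuracy`, and updates each belief with
#' [bayes_update()] starting from the symmetric prior 0.5. Beliefs converge
#' quickly toward the payoffs because signal evidence accumulates
#' multiplicatively in the likelihood ratio.
#'
#' @param payoffs binary vector of true payoffs (see
#'   [fixture_securities_payoffs()]).
#' @param config a [sampler_config()]; `mode` is ignored in this regime.
#' @return a `belief_trajectory` with a `trials x n_units` belief matrix
#'   (row `t` holds beliefs after trial `t`) and the signal matrix used.
#' @examples
#' tr <- simulate_securities_learning(fixture_securities_payoffs(),
#'                                    sampler_config(trials = 30, seed = 1))
#' tr$beliefs[30, ]
#' @export
simulate_securities_learning <- function(payoffs, config = sampler_config()) {
  stopifnot(all(payoffs %in% c(0, 1)))
  n <- length(payoffs)
  signals <- generate_signal_stream(payoffs, config$accuracy, config$trials,
                                    config$seed)
  beliefs <- matrix(NA_real_, config$trials, n)
  b <- rep(0.5, n)
  for (t in seq_len(config$trials)) {
    b <- bayes_update(b, signals[t, ], config$accuracy)
    beliefs[t, ] <- b
  }
  new_trajectory("securities", beliefs, config,
                 list(signals = signals, payoffs = payoffs))
}

#' Draw one randomly assembled knapsack
#'
#' Draws a maximal feasible selection using the current RNG state. In
#' `"sequential-fill"` mode, items are considered in uniformly random
#' order and each item that still fits is added; every item is considered
#' once, so the result is maximal but not uniformly distributed over
#' maximal selections. In `"uniform-maximal"` mode the selection is drawn
#' uniformly from [enumerate_maximal()] (which may be supplied precomputed
#' via `maximal_sets`).
#'
#' @param instance a [knapsack_instance()].
#' @param mode `"sequential-fill"` or `"uniform-maximal"`.
#' @param maximal_sets optional precomputed result of
#'   [enumerate_maximal()], used only in `"uniform-maximal"` mode.
#' @return an [item_selection()] that is feasible and maximal.
#' @export
sample_knapsack_fill <- function(instance,
                                 mode = c("sequential-fill", "uniform-maximal"),
                                 maximal_sets = NULL) {
  mode <- match.arg(mode)
  if (mode == "sequential-fill") {
    ord <- sample.int(instance$n)
    sel <- integer(0); wt <- 0
    for (j in ord) {
      if (wt + instance$weights[j] <= instance$capacity) {
        sel <- c(sel, j); wt <- wt + instance$weights[j]
      }
    }
    item_selection(instance, sel)
  } else {
    if (is.null(maximal_sets)) maximal_sets <- enumerate_maximal(instance)
    maximal_sets[[sample.int(length(maximal_sets), 1L)]]
  }
}

#' Simulate sampling-based learning on a knapsack instance
#'
#' The complexity-driven-uncertainty regime: in each trial the learner
#' draws a random capacity-filled knapsack ([sample_knapsack_fill()]),
#' compares its total value with the incumbent best value, emits
#' membership signals with [make_signals()] (from the sample if it
#' improved strictly, from the incumbent otherwise), and updates beliefs
#' with the running-mean rule [update_running_mean()]. Before trial 1 the
#' incumbent value is `-Inf`, so the first sample always counts as an
#' improvement; ties are treated as "not improved" and the incumbent is
#' retained.
#'
#' @param instance a [knapsack_instance()].
#' @param config a [sampler_config()].
#' @return a `belief_trajectory` with the belief matrix, per-trial
#'   `incumbent_value`, the list of `sampled_selections`, and the
#'   discovery record `found_optimum` / `first_hit_trial` (`NA` when the
#'   optimum value was never sampled).
#' @examples
#' tr <- simulate_sampling_learning(fixture_backpacking(),
#'                                  sampler_config("sequential-fill", seed = 1))
#' tr$incumbent_value
#' @export
simulate_sampling_learning <- function(instance, config = sampler_config()) {
  n <- instance$n
  maximal_sets <- if (config$mode == "uniform-maximal")
    enumerate_maximal(instance) else NULL
  opt_value <- solve_dp(instance)$optimal_value
  beliefs <- matrix(NA_real_, config$trials, n)
  incumbent_value <- numeric(config$trials)
  sampled <- vector("list", config$trials)
  with_seed(config$seed, {
    b <- rep(0.5, n)
    inc_val <- -Inf
    inc_sel <- integer(0)
    first_hit <- NA_integer_
    for (t in seq_len(config$trials)) {
      s <- sample_knapsack_fill(instance, config$mode, maximal_sets)
      sampled[[t]] <- s
      improved <- s$total_value > inc_val
      if (improved) { inc_val <- s$total_value; inc_sel <- s$indices }
      sig <- make_signals(s, inc_sel, improved, n)
      b <- update_running_mean(b, sig, t)
      beliefs[t, ] <- b
      incumbent_value[t] <- inc_val
      if (is.na(first_hit) && s$total_value == opt_value) first_hit <- t
    }
    new_trajectory("sampling", beliefs, config,
                   list(incumbent_value = incumbent_value,
                        sampled_selections = sampled,
                        optimal_value = opt_value,
                        found_optimum = !is.na(first_hit),
                        first_hit_trial = first_hit))
  })
}

#' Tabulate a belief trajectory in long form
#'
#' @param x a `belief_trajectory`.
#' @param row.names,optional,... ignored; present for the generic.
#' @return a data frame with columns `trial`, `unit` (1-based), `belief`,
#'   plus `incumbent_value` and `sampled_selection` (semicolon-joined
#'   indices) in the sampling regime.
#' @export
as.data.frame.belief_trajectory <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  df <- data.frame(
    trial = rep(seq_len(x$trials), each = x$n_units),
    unit = rep(seq_len(x$n_units), times = x$trials),
    belief = as.vector(t(x$beliefs)))
  if (x$regime == "sampling") {
    df$incumbent_value <- rep(x$incumbent_value, each = x$n_units)
    df$sampled_selection <- rep(
      vapply(x$sampled_selections,
             function(s) paste(s$indices, collapse = ";"), character(1)),
      each = x$n_units)
  }
  df
}

#' Write a trajectory to CSV
#'
#' Floating-point columns are written with 12 significant digits so that
#' repeated runs with the same seed produce byte-identical files.
#'
#' @param trajectory a `belief_trajectory`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  df$belief <- formatC(df$belief, digits = 12, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Machine-readable summary of a simulated run
#'
#' @param trajectory a `belief_trajectory`.
#' @param path optional path; when given, the summary is written as JSON.
#' @return a named list with `regime`, `mode`, `seed`, `trials`,
#'   `final_beliefs` and, for the sampling regime, `found_optimum` and
#'   `first_hit_trial`.
#' @export
run_summary <- function(trajectory, path = NULL) {
  out <- list(regime = trajectory$regime, mode = trajectory$mode,
              seed = trajectory$seed, trials = trajectory$trials,
              final_beliefs = signif(trajectory$beliefs[trajectory$trials, ], 12))
  if (trajectory$regime == "sampling") {
    out$found_optimum <- trajectory$found_optimum
    out$first_hit_trial <- trajectory$first_hit_trial
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
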
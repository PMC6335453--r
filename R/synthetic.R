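#' The 10-item backpacking instance
#'
#' The canonical worked example: 10 items with values
#' (31, 141, 46, 30, 74, 105, 119, 160, 59, 71), weights
#' (21, 97, 32, 21, 52, 75, 86, 116, 43, 54), capacity 265. Items 2, 5 and 8
#' form the unique optimal selection (value 375, weight exactly 265), the
#' plain greedy solution is items 1-5 (value 322), the Sahni-k complexity
#' is 3, and the instance has 82 maximal feasible (capacity-filled)
#' selections.
#'
#' @return a [knapsack_instance()].
#' @examples
#' fixture_backpacking()
#' @export
fixture_backpacking <- function() {
  knapsack_instance(
    values = c(31, 141, 46, 30, 74, 105, 119, 160, 59, 71),
    weights = c(21, 97, 32, 21, 52, 75, 86, 116, 43, 54),
    capacity = 265)
}

#' Final payoffs of the 10 securities
#'
#' The binary payoff vector of the securities-selection example: securities
#' 8, 9 and 10 pay 1, all others pay 0. Distinct from the optimal items
#' {2, 5, 8} of the backpacking instance -- the two examples are separate.
#'
#' @return a binary vector of length 10.
#' @examples
#' fixture_securities_payoffs()
#' @export
fixture_securities_payoffs <- function() {
  c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1)
}

#' Specification for a random knapsack instance generator
#'
#' The generator emulates the structure of the backpacking fixture:
#' weights drawn uniformly from an integer range and values tied to
#' weights through a value-to-weight density drawn near a target, giving
#' the strongly correlated regime in which greedy search fails and the
#' Sahni-k metric is informative. Larger `density_jitter` moves toward the
#' uncorrelated regime. Defaults mirror the fixture: densities around
#' 1.4 with spread 0.1 (the fixture's densities span 1.31-1.48) and
#' capacity 0.44 of total weight (265/597).
#'
#' @param n item count.
#' @param weight_range integer interval for weights (default `c(20, 120)`,
#'   the fixture's span).
#' @param density_target expected value-to-weight ratio (default 1.4).
#' @param density_jitter half-width of the uniform density spread
#'   (default 0.1).
#' @param capacity_fraction capacity as a fraction of total weight, in
#'   `(0, 1]` (default 0.44).
#' @param seed integer seed; the generated instance is a pure function of
#'   this spec.
#' @return an object of class `instance_gen_spec`.
#' @export
instance_gen_spec <- function(n, weight_range = c(20, 120),
                              density_target = 1.4, density_jitter = 0.1,
                              capacity_fraction = 0.44, seed = 1L) {
  if (n < 1 || n != trunc(n)) stop("instance_gen_spec: n must be a positive integer")
  if (length(weight_range) != 2L || weight_range[1] < 1 ||
      weight_range[2] < weight_range[1])
    stop("instance_gen_spec: weight_range must be an increasing positive interval")
  if (capacity_fraction <= 0 || capacity_fraction > 1)
    stop("instance_gen_spec: capacity_fraction must lie in (0, 1]")
  if (density_target - density_jitter <= 0)
    stop("instance_gen_spec: density_target - density_jitter must be positive")
  structure(list(n = as.integer(n), weight_range = as.integer(weight_range),
                 density_target = density_target, density_jitter = density_jitter,
                 capacity_fraction = capacity_fraction, seed = as.integer(seed)),
            class = "instance_gen_spec")
}

#' Generate a random knapsack instance
#'
#' Weights are drawn uniformly from `spec$weight_range`; each value is
#' `round(weight * density)` (floored at 1) with the density drawn
#' uniformly within `density_target +/- density_jitter`; the capacity is
#' `round(capacity_fraction * total weight)`. Fully determined by
#' `spec$seed`.
#'
#' @param spec an [instance_gen_spec()].
#' @return a [knapsack_instance()].
#' @examples
#' generate_instance(instance_gen_spec(n = 8, seed = 42))
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "instance_gen_spec"))
  with_seed(spec$seed, {
    w <- sample(spec$weight_range[1]:spec$weight_range[2], spec$n, replace = TRUE)
    dens <- stats::runif(spec$n, spec$density_target - spec$density_jitter,
                         spec$density_target + spec$density_jitter)
    v <- pmax(1, round(w * dens))
    capacity <- round(spec$capacity_fraction * sum(w))
    if (capacity < 1)
      stop("generate_instance: parameters produce a zero-capacity instance")
    knapsack_instance(v, w, capacity)
  })
}

#' Generate a Bernoulli signal stream
#'
#' A `trials x units` binary matrix in which the signal for unit `j` in
#' each trial independently equals `payoffs[j]` with probability `q` and
#' its complement otherwise. Within a trial the random stream is consumed
#' in unit order, so equal seeds reproduce the matrix exactly.
#'
#' @param payoffs binary payoff vector.
#' @param q signal accuracy in `(0, 1)`.
#' @param trials positive integer number of trials.
#' @param seed integer seed.
#' @return a `trials x units` matrix with entries in `{0, 1}`.
#' @examples
#' generate_signal_stream(fixture_securities_payoffs(), 0.7, 5, seed = 1)
#' @export
generate_signal_stream <- function(payoffs, q, trials, seed) {
  stopifnot(all(payoffs %in% c(0, 1)), q > 0, q < 1,
            trials >= 1, trials == trunc(trials))
  n <- length(payoffs)
  with_seed(seed, {
    u <- matrix(stats::runif(trials * n), nrow = trials, byrow = TRUE)
    match_payoff <- u < q
    sig <- matrix(rep(payoffs, each = trials), nrow = trials)
    sig[!match_payoff] <- 1 - sig[!match_payoff]
    sig
  })
}
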
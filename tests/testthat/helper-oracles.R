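# Shared test helpers: tiny random instances and independent brute-force
# oracles that never call the solver code paths they are used to check.

random_test_instance <- function(n, seed) {
  generate_instance(instance_gen_spec(n = n, seed = seed))
}

# independent oracle: maximum feasible value by direct enumeration of all
# index subsets (utils::combn, no bit tricks shared with the solvers)
oracle_optimum <- function(instance) {
  best <- 0
  for (m in seq_len(instance$n)) {
    for (s in utils::combn(instance$n, m, simplify = FALSE)) {
      if (sum(instance$weights[s]) <= instance$capacity)
        best <- max(best, sum(instance$values[s]))
    }
  }
  best
}

# independent oracle: all maximal feasible subsets by direct filtering
oracle_maximal_sets <- function(instance) {
  out <- list()
  subsets <- list(integer(0))
  for (m in seq_len(instance$n))
    subsets <- c(subsets, utils::combn(instance$n, m, simplify = FALSE))
  for (s in subsets) {
    wt <- sum(instance$weights[s])
    if (wt > instance$capacity) next
    rest <- setdiff(seq_len(instance$n), s)
    if (length(rest) == 0L || all(wt + instance$weights[rest] > instance$capacity))
      out[[length(out) + 1L]] <- sort(s)
  }
  out
}

# independent oracle: count total preorders on m elements by enumerating
# every binary relation and filtering for totality and transitivity
oracle_preorder_count <- function(m) {
  if (m == 0) return(1L)
  cnt <- 0L
  bits <- bitwShiftL(1L, 0:(m * m - 1L))
  for (code in 0:(2^(m * m) - 1L)) {
    R <- matrix(bitwAnd(code, bits) != 0L, m, m)
    if (!all(R | t(R))) next
    if (any((R %*% R > 0) & !R)) next
    cnt <- cnt + 1L
  }
  cnt
}
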
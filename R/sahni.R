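#' Greedy completion of a partial selection
#'
#' Starting from a feasible seed selection, scans the items not in the seed
#' in decreasing order of value-to-weight ratio (density), breaking density
#' ties in favour of the lower item index, and adds each item that still
#' fits. By default the scan continues past items that do not fit until
#' every item has been considered, so the result is maximal; with
#' `stop_at_first_misfit = TRUE` the scan terminates at the first item that
#' does not fit (a stricter reading of "terminates once the knapsack has
#' reached capacity", kept for sensitivity analysis).
#'
#' @param instance a [knapsack_instance()].
#' @param seed an [item_selection()] or integer index vector; must be
#'   feasible.
#' @param stop_at_first_misfit logical; see above. Default `FALSE`.
#' @return an [item_selection()] extending the seed.
#' @examples
#' greedy_fill(fixture_backpacking(), integer(0))  # items 1..5, value 322
#' @export
greedy_fill <- function(instance, seed = integer(0), stop_at_first_misfit = FALSE) {
  seed <- as_selection(instance, seed)
  if (seed$total_weight > instance$capacity)
    stop("greedy_fill: seed selection is infeasible")
  ord <- density_order(instance)
  sel <- seed$indices
  wt <- seed$total_weight
  for (j in setdiff(ord, sel)) {
    if (wt + instance$weights[j] <= instance$capacity) {
      sel <- c(sel, j)
      wt <- wt + instance$weights[j]
    } else if (stop_at_first_misfit) {
      break
    }
  }
  item_selection(instance, sel)
}

density_order <- function(instance) {
  order(-instance$values / instance$weights, seq_len(instance$n))
}

#' Sahni candidate solution at seed cardinality k
#'
#' The Sahni procedure enumerates seed subsets of at most `k` items,
#' discards infeasible seeds, completes each feasible seed greedily with
#' [greedy_fill()], and proposes the completion of highest total value.
#' At `k = 0` this is the plain greedy solution; at `k = n` the optimal
#' subset itself is among the seeds, so the candidate is optimal. Under
#' this cumulative seeding the candidate value is non-decreasing in `k`.
#' Setting `seed_cardinality = "exactly_k"` restricts seeds to exactly `k`
#' items (a literal reading under which neither property holds; provided
#' for sensitivity analysis).
#'
#' @param instance a [knapsack_instance()].
#' @param k integer seed cardinality bound, `0 <= k <= n`.
#' @param seed_cardinality `"at_most_k"` (default, the published procedure)
#'   or `"exactly_k"`.
#' @param stop_at_first_misfit passed to [greedy_fill()].
#' @return a `solve_result` whose `optimal_value` is the candidate value
#'   (not necessarily the true optimum); value ties among candidates are
#'   broken by the lexicographically smallest selection. `is_unique` is
#'   `NA` (the procedure does not certify uniqueness).
#' @examples
#' sahni_candidate(fixture_backpacking(), 1)$optimal_value  # 367
#' @export
sahni_candidate <- function(instance, k,
                            seed_cardinality = c("at_most_k", "exactly_k"),
                            stop_at_first_misfit = FALSE) {
  seed_cardinality <- match.arg(seed_cardinality)
  n <- instance$n
  if (length(k) != 1L || k < 0 || k > n || k != trunc(k))
    stop(sprintf("sahni_candidate: k must be an integer in 0..%d", n))
  cards <- if (seed_cardinality == "at_most_k") 0:k else k
  best_val <- -Inf
  best_sel <- NULL
  for (m in cards) {
    seeds <- if (m == 0L) list(integer(0)) else
      utils::combn(n, m, simplify = FALSE)
    for (s in seeds) {
      if (sum(instance$weights[s]) > instance$capacity) next
      cand <- greedy_fill(instance, s, stop_at_first_misfit)
      if (cand$total_value > best_val ||
          (cand$total_value == best_val &&
           selection_key(cand$indices) < selection_key(best_sel))) {
        best_val <- cand$total_value
        best_sel <- cand$indices
      }
    }
  }
  if (is.null(best_sel))
    stop("sahni_candidate: no feasible seed of the requested cardinality")
  res <- new_solve_result(instance, best_val, best_sel, NA, "sahni")
  res$k <- k
  res
}

#' Sahni-k instance complexity metric
#'
#' The smallest seed cardinality `k` at which the Sahni candidate solution
#' attains the instance's true optimum. `k = 0` means plain greedy solves
#' the instance; higher values indicate that more exhaustive seeding --
#' hence more computation and memory -- is needed, which is why the metric
#' serves as a per-instance measure of computational complexity. The
#' metric always exists because the optimal subset is a seed at `k = n`.
#'
#' @param instance a [knapsack_instance()]; the optimum is established with
#'   [solve_dp()].
#' @param stop_at_first_misfit passed to the greedy completion.
#' @return a single integer in `0..n`.
#' @examples
#' sahni_k(fixture_backpacking())  # 3
#' @export
sahni_k <- function(instance, stop_at_first_misfit = FALSE) {
  opt <- solve_dp(instance)$optimal_value
  for (k in 0:instance$n) {
    cand <- sahni_candidate(instance, k,
                            stop_at_first_misfit = stop_at_first_misfit)
    if (cand$optimal_value == opt) return(k)
  }
  stop("sahni_k: internal error; optimum not reached at k = n")
}
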
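#' @rdname solve_bruteforce
#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("optimal value %g via %s; items {%s}%s\n",
              x$optimal_value, x$method,
              paste(x$optimal_selection$indices, collapse = ","),
              if (x$is_unique) " (unique optimum)" else " (ties exist)"))
  invisible(x)
}

new_solve_result <- function(instance, value, indices, is_unique, method) {
  structure(
    list(optimal_value = value,
         optimal_selection = item_selection(instance, indices),
         is_unique = is_unique,
         method = method),
    class = "solve_result")
}

# total value/weight of every subset of the items, by iterative doubling;
# subsets are encoded as bit masks with item i on bit i-1
subset_totals <- function(x) {
  tot <- 0
  for (xi in x) tot <- c(tot, tot + xi)
  tot
}

mask_to_indices <- function(mask, n) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
}

#' Exact knapsack solvers
#'
#' Three exact solvers with a common result contract: the maximum total
#' value over all feasible item subsets, one attaining selection, and a
#' flag recording whether exactly one selection attains the optimum.
#'
#' `solve_bruteforce()` enumerates all `2^n` subsets (the oracle the other
#' solvers are tested against); it refuses instances with more than
#' `max_items` items. `solve_dp()` fills the standard pseudo-polynomial
#' value table over weights `0..capacity` with traceback; it refuses
#' instances whose table would exceed `max_cells` entries. When several
#' optimal selections exist the traceback prefers excluding
#' higher-indexed items, which makes the returned selection deterministic.
#' `solve_branch_and_bound()` performs depth-first search in decreasing
#' value-density order, pruning with the fractional-relaxation upper
#' bound.
#'
#' @param instance a [knapsack_instance()].
#' @param max_items refusal threshold for exhaustive enumeration
#'   (default 25).
#' @param max_cells refusal threshold for the dynamic-programming table,
#'   in table entries (default 2e7).
#' @return an object of class `solve_result` with fields `optimal_value`,
#'   `optimal_selection`, `is_unique` and `method`.
#' @examples
#' solve_bruteforce(fixture_backpacking())
#' @export
solve_bruteforce <- function(instance, max_items = 25L) {
  n <- instance$n
  if (n > max_items)
    stop(sprintf("solve_bruteforce: %d items exceeds the exhaustive-search guard of %d",
                 n, max_items))
  tv <- subset_totals(instance$values)
  tw <- subset_totals(instance$weights)
  feas <- tw <= instance$capacity
  opt <- max(tv[feas])
  hits <- which(feas & tv == opt) - 1L   # masks attaining the optimum
  sels <- lapply(hits, mask_to_indices, n = n)
  pick <- order(vapply(sels, selection_key, character(1)))[1]
  new_solve_result(instance, opt, sels[[pick]], length(hits) == 1L, "bruteforce")
}

# lexicographic sort key for a sorted index vector
selection_key <- function(idx) paste(sprintf("%04d", idx), collapse = " ")

#' @rdname solve_bruteforce
#' @export
solve_dp <- function(instance, max_cells = 2e7) {
  n <- instance$n; cap <- instance$capacity
  if ((cap + 1) * (n + 1) > max_cells)
    stop(sprintf("solve_dp: table of %g cells exceeds the budget of %g",
                 (cap + 1) * (n + 1), max_cells))
  w <- instance$weights; v <- instance$values
  # A[w+1]: best value among subsets of total weight exactly w; C: how many
  # subsets attain it. Stages are kept for the traceback.
  A <- c(0, rep(-Inf, cap))
  C <- c(1, rep(0, cap))
  stages <- vector("list", n + 1L)
  stages[[1L]] <- A
  for (i in seq_len(n)) {
    if (w[i] <= cap) {
      idx <- (cap + 1):(w[i] + 1)            # weights cap .. w[i]
      cand <- A[idx - w[i]] + v[i]
      better <- cand > A[idx]
      equal <- !better & cand == A[idx] & is.finite(cand)
      C[idx][equal] <- C[idx][equal] + C[idx - w[i]][equal]
      A[idx][better] <- cand[better]
      C[idx][better] <- C[idx - w[i]][better]
    }
    stages[[i + 1L]] <- A
  }
  opt <- max(A)
  is_unique <- sum(C[A == opt]) == 1
  # traceback: prefer leaving out higher-indexed items
  wt <- which(A == opt)[1] - 1
  val <- opt
  sel <- integer(0)
  for (i in n:1) {
    if (is.finite(stages[[i]][wt + 1]) && stages[[i]][wt + 1] == val) next
    sel <- c(sel, i)
    wt <- wt - w[i]; val <- val - v[i]
  }
  new_solve_result(instance, opt, rev(sel), is_unique, "dp")
}

#' @rdname solve_bruteforce
#' @export
solve_branch_and_bound <- function(instance) {
  n <- instance$n; cap <- instance$capacity
  ord <- order(-instance$values / instance$weights, seq_len(n))
  v <- instance$values[ord]; w <- instance$weights[ord]
  suffix_v <- rev(cumsum(rev(v))); suffix_w <- rev(cumsum(rev(w)))

  # fractional-relaxation upper bound for the subproblem at position i
  frac_bound <- function(i, wt, val) {
    room <- cap - wt
    while (i <= n) {
      if (w[i] <= room) { room <- room - w[i]; val <- val + v[i]; i <- i + 1L }
      else return(val + v[i] * room / w[i])
    }
    val
  }

  best <- -Inf; best_sel <- integer(0)
  n_opt <- 0L

  dfs <- function(i, wt, val, taken) {
    if (i > n) {
      if (val > best) { best <<- val; best_sel <<- taken; n_opt <<- 1L }
      else if (val == best) n_opt <<- n_opt + 1L
      return(invisible())
    }
    if (frac_bound(i, wt, val) < best) return(invisible())
    if (wt + w[i] <= cap) dfs(i + 1L, wt + w[i], val + v[i], c(taken, ord[i]))
    dfs(i + 1L, wt, val, taken)
  }
  dfs(1L, 0, 0, integer(0))

  # n_opt undercounts ties found before the incumbent reached the optimum,
  # so the uniqueness flag comes from a second, exact counting pass
  count <- 0L
  count_dfs <- function(i, wt, val) {
    if (count >= 2L) return(invisible())
    if (i > n) { if (val == best) count <<- count + 1L; return(invisible()) }
    if (frac_bound(i, wt, val) < best) return(invisible())
    if (wt + w[i] <= cap) count_dfs(i + 1L, wt + w[i], val + v[i])
    count_dfs(i + 1L, wt, val)
  }
  count_dfs(1L, 0, 0)
  new_solve_result(instance, best, sort(best_sel), count == 1L, "branch_and_bound")
}

#' Enumerate all maximal feasible (capacity-filled) selections
#'
#' A selection is capacity-filled when it is feasible and no excluded item
#' can be added without exceeding the capacity. These are the distinct
#' stopping points of any "add items until nothing fits" procedure, so
#' their count is the denominator of the uniform per-trial discovery
#' probability in the sampling model of learning.
#'
#' @param instance a [knapsack_instance()] with at most `max_items` items.
#' @param max_items enumeration guard (default 20).
#' @return a list of [item_selection()] objects in lexicographic order of
#'   their index sets.
#' @examples
#' length(enumerate_maximal(fixture_backpacking()))  # 82
#' @export
enumerate_maximal <- function(instance, max_items = 20L) {
  n <- instance$n
  if (n > max_items)
    stop(sprintf("enumerate_maximal: %d items exceeds the enumeration guard of %d",
                 n, max_items))
  tv <- subset_totals(instance$values)
  tw <- subset_totals(instance$weights)
  feas <- tw <= instance$capacity
  slack <- instance$capacity - tw
  masks <- 0:(2^n - 1L)
  blocked <- rep(FALSE, length(masks))
  for (j in seq_len(n)) {
    excluded <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) == 0L
    blocked <- blocked | (excluded & feas & instance$weights[j] <= slack)
  }
  hits <- masks[feas & !blocked]
  sels <- lapply(hits, mask_to_indices, n = n)
  sels <- sels[order(vapply(sels, selection_key, character(1)))]
  lapply(sels, function(idx) item_selection(instance, idx))
}

#' Write an enumeration of maximal selections to CSV
#'
#' Columns: `selection` (semicolon-joined 1-based indices), `total_value`,
#' `total_weight`, `is_optimal`.
#'
#' @param instance a [knapsack_instance()].
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_maximal_csv <- function(instance, path) {
  sels <- enumerate_maximal(instance)
  opt <- solve_dp(instance)$optimal_value
  df <- data.frame(
    selection = vapply(sels, function(s) paste(s$indices, collapse = ";"), character(1)),
    total_value = vapply(sels, function(s) s$total_value, numeric(1)),
    total_weight = vapply(sels, function(s) s$total_weight, numeric(1)))
  df$is_optimal <- df$total_value == opt
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
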
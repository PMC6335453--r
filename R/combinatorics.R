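#' Stirling numbers of the second kind
#'
#' `S(n, k)` counts the partitions of an `n`-element set into `k` nonempty
#' blocks, computed exactly via the recurrence
#' `S(n, k) = k S(n-1, k) + S(n-1, k-1)` with `S(0, 0) = 1`.
#'
#' @param n,k nonnegative integers with `k <= n`.
#' @return a [bignat()] (exact at every size).
#' @examples
#' as.numeric(stirling2(10, 3))
#' @export
stirling2 <- function(n, k) {
  if (n < 0 || k < 0 || n != trunc(n) || k != trunc(k))
    stop("stirling2: n and k must be nonnegative integers")
  if (k > n) stop("stirling2: k must not exceed n")
  stirling2_row(n)[[k + 1L]]
}

# full row S(n, 0..n) as a list of bignat
stirling2_row <- function(n) {
  row <- list(bignat(1))                       # S(0, 0)
  if (n == 0) return(row)
  for (m in seq_len(n)) {
    new <- vector("list", m + 1L)
    new[[1L]] <- bignat(0)                     # S(m, 0)
    for (k in seq_len(m)) {
      above <- if (k <= m - 1L) row[[k + 1L]] else bignat(0)
      new[[k + 1L]] <- bignat(k) * above + row[[k]]
    }
    row <- new
  }
  row
}

#' Number of weak orders (total preorders) on n alternatives
#'
#' A weak order is a complete, transitive ranking that allows ties -- the
#' structure a decision-maker's preferences must form over all available
#' options for the completeness axiom to hold. The count is the ordered
#' Bell (Fubini) number `sum_k k! S(n, k)`, which for `n = 10` equals
#' 102 247 563 -- the number of pairwise rankings a chooser over ten goods
#' must be prepared to resolve.
#'
#' @param n nonnegative integer number of alternatives.
#' @return a [bignat()].
#' @examples
#' as.numeric(weak_order_count(10))  # 102247563
#' @export
weak_order_count <- function(n) {
  if (n < 0 || n != trunc(n)) stop("weak_order_count: n must be a nonnegative integer")
  row <- stirling2_row(n)
  total <- bignat(0)
  kfact <- bignat(1)
  for (k in 0:n) {
    if (k > 0) kfact <- kfact * bignat(k)
    total <- total + kfact * row[[k + 1L]]
  }
  total
}

#' Number of subsets of n goods
#'
#' `2^n`, exactly, at any `n`.
#'
#' @param n nonnegative integer.
#' @return a [bignat()].
#' @examples
#' as.numeric(subset_count(10))  # 1024
#' @export
subset_count <- function(n) {
  if (n < 0 || n != trunc(n)) stop("subset_count: n must be a nonnegative integer")
  bignat(2)^n
}

#' Size of the joint state space over units and periods
#'
#' With `n_units` binary-payoff securities observed over `n_periods`
#' periods, the joint state space has `2^(n_units * n_periods)` elements
#' (for example `2^300` for 10 securities over 30 periods), computed as an
#' exact integer.
#'
#' @param n_units,n_periods positive integers.
#' @return a [bignat()].
#' @examples
#' state_space_size(10, 1)  # 1024
#' @export
state_space_size <- function(n_units, n_periods) {
  if (n_units < 1 || n_periods < 1 ||
      n_units != trunc(n_units) || n_periods != trunc(n_periods))
    stop("state_space_size: both arguments must be positive integers")
  subset_count(n_units * n_periods)
}

#' Combinatoric summary of a choice situation
#'
#' Collects the exact counts for `n` goods observed over `n_periods`
#' periods: the number of subsets, the number of weak orders (equivalently,
#' the maximum number of binary comparisons needed for a complete
#' preference ranking), and the state-space sizes per period and in total.
#' Counts exceeding 2^53 are reported as decimal strings so that no
#' precision is lost.
#'
#' @param n number of goods/securities.
#' @param n_periods number of observation periods (default 1).
#' @return a named list with elements `n`, `subsets`, `weak_orders`,
#'   `states_per_period`, `states_total`.
#' @examples
#' combinatorics_report(10, 30)
#' @export
combinatorics_report <- function(n, n_periods = 1) {
  list(
    n = n,
    subsets = bignat_json(subset_count(n)),
    weak_orders = bignat_json(weak_order_count(n)),
    states_per_period = bignat_json(subset_count(n)),
    states_total = bignat_json(subset_count(n * n_periods)))
}

# number when exactly representable as a double, decimal string otherwise
bignat_json <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (v <= 2^53 && bignat(v) == x) v else as.character(x)
}
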
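#' Construct a 0-1 knapsack instance
#'
#' An instance is a set of indivisible items, each with a positive integer
#' value and weight, together with a weight capacity. The optimization task
#' is to pick the subset of items of maximum total value whose total weight
#' does not exceed the capacity.
#'
#' @param values positive integer vector of item values.
#' @param weights positive integer vector of item weights, same length as
#'   `values`.
#' @param capacity nonnegative integer weight capacity. Zero is permitted so
#'   that degenerate instances (nothing fits) can be expressed.
#' @return an object of class `knapsack_instance` with fields `values`,
#'   `weights`, `capacity` and `n`.
#' @examples
#' inst <- knapsack_instance(c(10, 20), c(5, 12), 15)
#' inst$n
#' @seealso [fixture_backpacking()] for the canonical 10-item example.
#' @export
knapsack_instance <- function(values, weights, capacity) {
  if (length(values) != length(weights) || length(values) == 0L)
    stop("values and weights must have equal, nonzero length")
  if (any(values <= 0) || any(values != trunc(values)))
    stop("all item values must be positive integers")
  if (any(weights <= 0) || any(weights != trunc(weights)))
    stop("all item weights must be positive integers")
  if (length(capacity) != 1L || capacity < 0 || capacity != trunc(capacity))
    stop("capacity must be a single nonnegative integer")
  structure(
    list(values = as.numeric(values), weights = as.numeric(weights),
         capacity = as.numeric(capacity), n = length(values)),
    class = "knapsack_instance")
}

#' @export
print.knapsack_instance <- function(x, ...) {
  cat(sprintf("0-1 knapsack instance: %d items, capacity %g\n", x$n, x$capacity))
  cat(sprintf("  total value %g, total weight %g\n", sum(x$values), sum(x$weights)))
  invisible(x)
}

#' Construct an item selection
#'
#' A selection is a subset of an instance's items, identified by 1-based
#' indices, with its derived total value and weight.
#'
#' @param instance a [knapsack_instance()].
#' @param indices integer vector of distinct 1-based item positions (may be
#'   empty).
#' @return an object of class `item_selection` with fields `indices`
#'   (sorted), `total_value` and `total_weight`.
#' @export
item_selection <- function(instance, indices) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be distinct")
  if (length(indices) > 0 && (any(indices < 1L) || any(indices > instance$n)))
    stop(sprintf("selection index out of range 1..%d", instance$n))
  indices <- sort(indices)
  structure(
    list(indices = indices,
         total_value = sum(instance$values[indices]),
         total_weight = sum(instance$weights[indices])),
    class = "item_selection")
}

#' @export
print.item_selection <- function(x, ...) {
  cat(sprintf("items {%s}: value %g, weight %g\n",
              paste(x$indices, collapse = ","), x$total_value, x$total_weight))
  invisible(x)
}

# accept either an item_selection or a bare index vector
as_selection <- function(instance, sel) {
  if (inherits(sel, "item_selection")) sel else item_selection(instance, sel)
}

#' Feasibility of a selection
#'
#' A selection is feasible when its total weight does not exceed the
#' instance's capacity.
#'
#' @param instance a [knapsack_instance()].
#' @param sel an [item_selection()] or an integer vector of 1-based indices.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_feasible(fixture_backpacking(), c(2, 5, 8))
#' @export
is_feasible <- function(instance, sel) {
  sel <- as_selection(instance, sel)
  sel$total_weight <= instance$capacity
}

#' Maximality (capacity-filledness) of a selection
#'
#' A feasible selection is maximal -- a "capacity-filled" knapsack -- when
#' no excluded item can be added without exceeding the capacity. The set of
#' maximal selections is finite and is the sample space of the uniform
#' sampling model (see [enumerate_maximal()]).
#'
#' @inheritParams is_feasible
#' @return `TRUE` or `FALSE`. An infeasible input selection is an error.
#' @examples
#' is_maximal(fixture_backpacking(), c(2, 5, 8))
#' @export
is_maximal <- function(instance, sel) {
  sel <- as_selection(instance, sel)
  if (sel$total_weight > instance$capacity)
    stop("is_maximal: selection is infeasible")
  out <- setdiff(seq_len(instance$n), sel$indices)
  length(out) == 0L ||
    all(sel$total_weight + instance$weights[out] > instance$capacity)
}

#' Read a knapsack instance from a file
#'
#' Two plain-text dialects are accepted and auto-detected. The classic
#' OR-library dialect: line 1 holds `n capacity`, followed by `n` lines of
#' `value weight`. The CSV dialect: a comment line `# capacity: C` followed
#' by a header `item,value,weight` and one row per item.
#'
#' @param path path to the instance file.
#' @return a [knapsack_instance()].
#' @export
read_instance <- function(path) {
  if (!file.exists(path)) stop(sprintf("instance file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("%s: empty instance file", path))
  if (grepl(",", lines[min(2L, length(lines))]) || grepl("^#", lines[1])) {
    return(read_instance_csv(path, lines))
  }
  head <- suppressWarnings(as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(head) != 2L || anyNA(head))
    stop(sprintf("%s: line 1: expected 'n capacity'", path))
  n <- head[1]; capacity <- head[2]
  if (length(lines) < n + 1)
    stop(sprintf("%s: expected %d item lines, found %d", path, n, length(lines) - 1L))
  vals <- numeric(n); wts <- numeric(n)
  for (i in seq_len(n)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]))
    if (length(row) != 2L || anyNA(row))
      stop(sprintf("%s: line %d: expected 'value weight'", path, i + 1L))
    vals[i] <- row[1]; wts[i] <- row[2]
  }
  knapsack_instance(vals, wts, capacity)
}

read_instance_csv <- function(path, lines) {
  capline <- grep("^#\\s*capacity\\s*:", lines, value = TRUE)
  if (length(capline) != 1L)
    stop(sprintf("%s: CSV dialect requires one '# capacity: C' comment line", path))
  capacity <- suppressWarnings(as.numeric(sub("^#\\s*capacity\\s*:\\s*", "", capline)))
  if (is.na(capacity)) stop(sprintf("%s: unparseable capacity comment", path))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("item", "value", "weight")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: CSV header must contain columns item,value,weight", path))
  df <- df[order(df$item), ]
  knapsack_instance(df$value, df$weight, capacity)
}

#' Write a knapsack instance to a file
#'
#' @inheritParams read_instance
#' @param instance a [knapsack_instance()].
#' @param format `"orlib"` (default; `n capacity` then `value weight` lines)
#'   or `"csv"` (`# capacity:` comment, then `item,value,weight` rows).
#' @return the path, invisibly.
#' @export
write_instance <- function(instance, path, format = c("orlib", "csv")) {
  format <- match.arg(format)
  if (format == "orlib") {
    lines <- c(sprintf("%d %g", instance$n, instance$capacity),
               sprintf("%g %g", instance$values, instance$weights))
  } else {
    lines <- c(sprintf("# capacity: %g", instance$capacity),
               "item,value,weight",
               sprintf("%d,%g,%g", seq_len(instance$n), instance$values,
                       instance$weights))
  }
  writeLines(lines, path)
  invisible(path)
}
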
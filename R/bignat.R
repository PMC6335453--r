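#' Exact nonnegative big integers
#'
#' Counting results in this package (numbers of weak orders, powers of two
#' for state spaces) grow far beyond 2^53, the largest range over which
#' doubles are exact. `bignat` stores a nonnegative integer as a vector of
#' base-10^6 limbs (least significant first) held in doubles, so every
#' intermediate product stays well inside the exactly-representable range.
#' Arithmetic (`+`, `*`, comparisons) is available through the usual
#' operators; mixed operands are coerced with [bignat()].
#'
#' @param x a single nonnegative whole number (exactly representable as a
#'   double, i.e. below 2^53), a decimal digit string, or a `bignat`.
#' @return an object of class `bignat`.
#' @examples
#' bignat(2)^10
#' bignat("102247563") == 102247563
#' @export
bignat <- function(x) {
  if (inherits(x, "bignat")) return(x)
  if (is.character(x)) {
    if (length(x) != 1L || !grepl("^[0-9]+$", x))
      stop("bignat: character input must be a single decimal digit string")
    s <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(s)
    starts <- seq(n, 1L, by = -6L)
    limbs <- vapply(starts, function(i) {
      as.numeric(substr(s, max(1L, i - 5L), i))
    }, numeric(1))
    return(new_bignat(limbs))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != trunc(x))
    stop("bignat: input must be a single nonnegative whole number")
  if (x > 2^53) stop("bignat: numeric input too large to be exact; pass a digit string")
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% 1e6)
    x <- (x - x %% 1e6) / 1e6
    if (x == 0) break
  }
  new_bignat(limbs)
}

BIGNAT_BASE <- 1e6

new_bignat <- function(limbs) {
  while (length(limbs) > 1L && limbs[length(limbs)] == 0) limbs <- limbs[-length(limbs)]
  if (length(limbs) == 0L) limbs <- 0
  structure(limbs, class = "bignat")
}

# propagate carries; limbs may temporarily exceed the base but never 2^53
bignat_carry <- function(limbs) {
  i <- 1L
  while (i <= length(limbs)) {
    if (limbs[i] >= BIGNAT_BASE) {
      carry <- floor(limbs[i] / BIGNAT_BASE)
      limbs[i] <- limbs[i] - carry * BIGNAT_BASE
      if (i == length(limbs)) limbs <- c(limbs, 0)
      limbs[i + 1L] <- limbs[i + 1L] + carry
    }
    i <- i + 1L
  }
  limbs
}

bignat_add <- function(a, b) {
  n <- max(length(a), length(b))
  s <- c(unclass(a), numeric(n - length(a))) + c(unclass(b), numeric(n - length(b)))
  new_bignat(bignat_carry(s))
}

bignat_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if ((length(a) == 1L && a == 0) || (length(b) == 1L && b == 0)) return(new_bignat(0))
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    res[idx] <- res[idx] + a[i] * b
    # keep partial sums far from 2^53: products are < 1e12, so re-carry
    # whenever enough terms have accumulated
    if (i %% 1000L == 0L) res <- c(bignat_carry(res), 0)[seq_along(res)]
  }
  new_bignat(bignat_carry(res))
}

#' @export
Ops.bignat <- function(e1, e2) {
  if (.Generic %in% c("+", "*", "==", "!=", "<", "<=", ">", ">=")) {
    a <- bignat(e1); b <- bignat(e2)
    switch(.Generic,
      "+"  = bignat_add(a, b),
      "*"  = bignat_mul(a, b),
      "==" = bignat_cmp(a, b) == 0L,
      "!=" = bignat_cmp(a, b) != 0L,
      "<"  = bignat_cmp(a, b) <  0L,
      "<=" = bignat_cmp(a, b) <= 0L,
      ">"  = bignat_cmp(a, b) >  0L,
      ">=" = bignat_cmp(a, b) >= 0L)
  } else if (.Generic == "^") {
    bignat_pow(bignat(e1), e2)
  } else {
    stop(sprintf("operation '%s' is not defined for bignat", .Generic))
  }
}

bignat_cmp <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0L
}

bignat_pow <- function(base, exp) {
  if (!is.numeric(exp) || length(exp) != 1L || exp < 0 || exp != trunc(exp))
    stop("bignat: exponent must be a single nonnegative whole number")
  out <- bignat(1)
  sq <- base
  while (exp > 0) {
    if (exp %% 2 == 1) out <- bignat_mul(out, sq)
    exp <- exp %/% 2
    if (exp > 0) sq <- bignat_mul(sq, sq)
  }
  out
}

#' @export
format.bignat <- function(x, ...) {
  limbs <- rev(unclass(x))
  paste0(limbs[1], paste(sprintf("%06d", limbs[-1]), collapse = ""))
}

#' @export
as.character.bignat <- function(x, ...) format(x)

#' @export
print.bignat <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.double.bignat <- function(x, ...) {
  v <- sum(unclass(x) * BIGNAT_BASE^(seq_along(unclass(x)) - 1L))
  if (v > 2^53) {
    warning("bignat value exceeds 2^53; conversion to double is inexact")
  }
  v
}
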
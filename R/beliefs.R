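#' Bayesian update of a binary-payoff belief from one signal
#'
#' Posterior probability that a unit pays off, after observing one binary
#' signal of accuracy `q` (the signal matches the true payoff with
#' probability `q`). For signal 1 the posterior is
#' `b q / (b q + (1-b)(1-q))`; for signal 0 it is
#' `b (1-q) / (b (1-q) + (1-b) q)`. Degenerate beliefs 0 and 1 are
#' absorbing: the formula returns them unchanged.
#'
#' @param belief prior probability (or vector of probabilities) in `[0,1]`.
#' @param signal 0 or 1 (recycled against `belief`).
#' @param q signal accuracy in `(0,1)`.
#' @return posterior probability, same length as `belief`.
#' @examples
#' bayes_update(0.5, 1, 0.7)  # 0.7
#' @export
bayes_update <- function(belief, signal, q) {
  stopifnot(all(belief >= 0 & belief <= 1), all(signal %in% c(0, 1)),
            length(q) == 1L, q > 0, q < 1)
  like1 <- ifelse(signal == 1, q, 1 - q)
  like0 <- ifelse(signal == 1, 1 - q, q)
  belief * like1 / (belief * like1 + (1 - belief) * like0)
}

#' Closed-form posterior after counted signals
#'
#' After `n_pos` positive and `n_neg` negative conditionally independent
#' signals of accuracy `q`, the posterior depends on the counts only
#' through their difference:
#' `1 / (1 + ((1-q)/q)^(n_pos - n_neg) * (1-prior)/prior)`.
#' Serves as the algebraic oracle for sequential [bayes_update()] chains.
#'
#' @param prior prior probability in `(0,1)`.
#' @param n_pos,n_neg nonnegative signal counts.
#' @param q signal accuracy in `(0,1)`.
#' @return posterior probability.
#' @examples
#' bayes_closed_form(0.5, 2, 0, 0.7)  # 49/58
#' @export
bayes_closed_form <- function(prior, n_pos, n_neg, q) {
  stopifnot(prior > 0, prior < 1, q > 0, q < 1, n_pos >= 0, n_neg >= 0)
  1 / (1 + ((1 - q) / q)^(n_pos - n_neg) * (1 - prior) / prior)
}

#' Running-mean belief update of the sampling regime
#'
#' The sampling-based learner weighs the previous belief by `(t-1)/t` and
#' the current signal by `1/t`, so the belief after trial `t` equals the
#' arithmetic mean of the signals emitted in trials `1..t`; the prior's
#' weight vanishes at `t = 1`.
#'
#' @param belief numeric vector of current beliefs.
#' @param signal binary vector, same length.
#' @param t trial index, `t >= 1`.
#' @return updated belief vector.
#' @examples
#' update_running_mean(c(0.5, 0.5), c(1, 0), t = 1)  # the signal itself
#' @export
update_running_mean <- function(belief, signal, t) {
  if (length(t) != 1L || t < 1 || t != trunc(t))
    stop("update_running_mean: t must be a positive integer trial index")
  ((t - 1) * belief + signal) / t
}

#' Signals emitted by the incumbent-comparison rule
#'
#' In the sampling regime, the learner compares the sampled selection's
#' value with the incumbent (best-so-far) value. If the sample improved on
#' the incumbent, the signal for item `i` is 1 when `i` is in the current
#' sample; otherwise the signal is 1 when `i` is in the incumbent
#' selection.
#'
#' @param current [item_selection()] or index vector: the sampled selection.
#' @param incumbent [item_selection()] or index vector: the best-so-far
#'   selection.
#' @param improved logical: did the current sample strictly improve on the
#'   incumbent?
#' @param n number of items/units.
#' @return a binary vector of length `n`.
#' @examples
#' make_signals(c(2, 5, 8), c(1), improved = TRUE, n = 10)
#' @export
make_signals <- function(current, incumbent, improved, n) {
  pick <- if (isTRUE(improved)) current else incumbent
  idx <- if (inherits(pick, "item_selection")) pick$indices else as.integer(pick)
  as.numeric(seq_len(n) %in% idx)
}

#' Probability of discovering the optimum within T trials
#'
#' With independent trials each succeeding with probability `p`, the chance
#' of at least one success in `T` trials is `1 - (1 - p)^T`.
#'
#' @param p per-trial success probability in `[0,1]`.
#' @param trials nonnegative integer number of trials.
#' @return a probability.
#' @examples
#' discovery_probability(1 / 82, 30)  # about 0.308
#' @export
discovery_probability <- function(p, trials) {
  stopifnot(p >= 0, p <= 1, trials >= 0, trials == trunc(trials))
  1 - (1 - p)^trials
}

#' Trials needed to reach a target discovery confidence
#'
#' The smallest integer `T` with `1 - (1 - p)^T >= confidence`, i.e. the
#' ceiling of `log(1 - confidence) / log(1 - p)` (guarded against
#' floating-point edge cases by checking the neighbouring integers).
#'
#' @param p per-trial success probability in `(0,1)`.
#' @param confidence target confidence in `(0,1)`.
#' @return a positive integer.
#' @examples
#' trials_for_confidence(1 / 82, 0.95)  # 244
#' @export
trials_for_confidence <- function(p, confidence) {
  stopifnot(p > 0, p < 1, confidence > 0, confidence < 1)
  t0 <- ceiling(log(1 - confidence) / log(1 - p))
  while (t0 > 1 && discovery_probability(p, t0 - 1) >= confidence) t0 <- t0 - 1
  while (discovery_probability(p, t0) < confidence) t0 <- t0 + 1
  as.integer(t0)
}
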
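#' Randomized (conformal) p-value of a score
#'
#' Rank-based tail probability of the current score among all scores of the
#' segment, with uniform tie-breaking:
#' `p_hat = (#\{j: s_j > s_i\} + theta * #\{j: s_j = s_i\}) / i`,
#' where `j` runs over all `i` scores *including the current one*, so the tie
#' count is at least 1 and `p_hat > 0` whenever `theta > 0`. (Counting only
#' strictly earlier ties would allow `p_hat = 0` at a new maximum score,
#' making the martingale betting factor infinite; self-inclusion is the
#' standard randomized conformal construction and guarantees `p_hat` in
#' `(0, 1]`.) Under exchangeable continuous scores, `p_hat` is Uniform(0, 1).
#'
#' @param history Numeric vector of the previous scores `s_1 ... s_(i-1)` in
#'   the segment (may be empty).
#' @param s_i Current score.
#' @param theta Tie-breaking draw in `[0, 1]`.
#' @return p-value in `(0, 1]` (given `theta > 0`).
#' @export
#' @examples
#' randomized_pvalue(c(5, 1), 3, theta = 0.7)  # (1 + 0.7 * 1) / 3
randomized_pvalue <- function(history, s_i, theta) {
  stopifnot(theta >= 0, theta <= 1)
  i <- length(history) + 1L
  greater <- sum(history > s_i)
  equal <- sum(history == s_i) + 1L  # self-inclusive
  (greater + theta * equal) / i
}

#' Power-martingale betting factor
#'
#' `xi * p_hat^(xi - 1)` for `xi` in (0, 1): greater than 1 when the p-value
#' is small (score unusually large), less than 1 otherwise; its integral over
#' `p_hat` in (0, 1] is 1, which is what makes the running product a
#' martingale under exchangeability.
#'
#' @param p_hat p-value in `(0, 1]`.
#' @param xi Power parameter in `(0, 1)` (default 0.8).
#' @param log If `TRUE`, return the log factor `log(xi) + (xi - 1) * log(p_hat)`.
#' @return Positive factor (or its log).
#' @export
martingale_factor <- function(p_hat, xi = 0.8, log = FALSE) {
  stopifnot(xi > 0, xi < 1)
  if (any(p_hat <= 0)) stop("`p_hat` must be > 0.", call. = FALSE)
  lf <- base::log(xi) + (xi - 1) * base::log(p_hat)
  if (log) lf else exp(lf)
}

#' Create a fresh martingale state
#'
#' The Randomized Power Martingale starts at `M = 1` (`log_M = 0`) with an
#' empty score history. The tie-breaking draws `theta_i ~ Uniform(0, 1)` come
#' from R's global random number generator; seed it (`set.seed()`) for
#' reproducible trajectories.
#'
#' @param xi Power parameter in `(0, 1)` (default 0.8; any value in
#'   `[0.8, 1)` behaves similarly).
#' @return A `martingale_state` list.
#' @export
new_martingale_state <- function(xi = 0.8) {
  stopifnot(xi > 0, xi < 1)
  structure(
    list(log_M = 0, xi = xi, history = numeric(0)),
    class = "martingale_state"
  )
}

# log-domain cap: exp(+-700) is near the double range; any sane threshold
# is crossed long before the cap matters.
LOG_M_CAP <- 700

#' Advance the martingale by one score
#'
#' Draws `theta`, computes the randomized p-value of `s_t` against the
#' segment's score history, multiplies the martingale by the betting factor
#' (accumulated in the log domain, capped at `exp(+-700)`), and appends the
#' score. Each update is a single O(history) pass; earlier factors are never
#' recomputed.
#'
#' @param state A `martingale_state`.
#' @param s_t New anomaly score.
#' @param theta Optional tie-breaking value; drawn from the global RNG if
#'   `NULL`.
#' @return `list(state = <updated>, M = <martingale value>, p_hat = <p-value>)`.
#' @export
martingale_update <- function(state, s_t, theta = NULL) {
  if (is.null(theta)) theta <- stats::runif(1)
  p_hat <- randomized_pvalue(state$history, s_t, theta)
  state$log_M <- state$log_M + martingale_factor(p_hat, state$xi, log = TRUE)
  state$log_M <- max(min(state$log_M, LOG_M_CAP), -LOG_M_CAP)
  state$history <- c(state$history, s_t)
  list(state = state, M = exp(state$log_M), p_hat = p_hat)
}

#' Has the martingale crossed the decision threshold?
#'
#' The null (no change) region is `M < lambda`; the alternative fires at
#' `M >= lambda` (inclusive).
#'
#' @param state A `martingale_state`.
#' @param lambda Threshold, strictly greater than 1.
#' @return `TRUE` iff `M >= lambda`.
#' @export
martingale_exceeds <- function(state, lambda) {
  if (!is.numeric(lambda) || lambda <= 1) {
    stop("`lambda` must be > 1.", call. = FALSE)
  }
  exp(state$log_M) >= lambda
}

#' Martingale trajectory over a score sequence (no resets)
#'
#' Convenience wrapper running [martingale_update()] over a whole score
#' vector; used for null-calibration studies and diagnostics.
#'
#' @param scores Numeric vector of anomaly scores.
#' @param xi Power parameter (default 0.8).
#' @return Tibble with columns `i`, `s`, `p_hat`, `M`.
#' @export
#' @examples
#' set.seed(1)
#' rpm_trajectory(abs(rnorm(20)))
rpm_trajectory <- function(scores, xi = 0.8) {
  stopifnot(xi > 0, xi < 1)
  n <- length(scores)
  # same counting as martingale_update(), with a preallocated history and
  # vectorized comparisons (the stateful path reallocates per update)
  theta <- stats::runif(n)
  p_hat <- numeric(n)
  for (i in seq_len(n)) {
    prev <- scores[seq_len(i - 1L)]
    p_hat[i] <- (sum(prev > scores[i]) +
                   theta[i] * (sum(prev == scores[i]) + 1L)) / i
  }
  log_M <- cumsum(base::log(xi) + (xi - 1) * base::log(p_hat))
  log_M <- pmin(pmax(log_M, -LOG_M_CAP), LOG_M_CAP)
  tibble::tibble(i = seq_len(n), s = scores, p_hat = p_hat, M = exp(log_M))
}
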
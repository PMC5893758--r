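#' Anomaly-state machinery: online residuals and strangeness scores
#'
#' The feature series is modelled, within each monitoring segment, by a
#' zero-trend autoregressive mean model `q_t = mu + e_t` (the trend is pinned
#' at 0 because EEG-derived features oscillate around a stable level). Rather
#' than re-fitting `mu` at every step, the one-step prediction is the running
#' segment mean `q_bar`; the prediction error `e_t = |q_t - q_hat_t|` is
#' standardized online against the running mean and standard deviation of past
#' errors, and the strangeness score is the distance of the standardized
#' residual `z_t` from the running mean `H` of past residuals.
#'
#' All statistics are *causal*: the value emitted at time `t` uses only data
#' observed strictly before (for standardization and `H`) or up to (for the
#' error) time `t`, so the pipeline can run on a live stream. Warm-up values
#' with no history are 0 by convention.
#'
#' @name anomaly-state
NULL

#' Create a fresh anomaly state
#'
#' @param epsilon Guard for division by a zero error standard deviation
#'   (default `1e-8`).
#' @return An `anomaly_state` list of zeroed running statistics.
#' @export
new_anomaly_state <- function(epsilon = 1e-8) {
  structure(
    list(
      count = 0L, q_bar = 0,              # running mean of q
      e_count = 0L, e_mean = 0, e_m2 = 0, # Welford accumulators for errors
      z_count = 0L, H = 0,                # running mean of standardized residuals
      epsilon = epsilon
    ),
    class = "anomaly_state"
  )
}

#' @describeIn new_anomaly_state Reset to a fresh state (keeps `epsilon`);
#'   equivalent to constructing a new state.
#' @param state An `anomaly_state`.
#' @export
reset_anomaly_state <- function(state) new_anomaly_state(state$epsilon)

#' One-step prediction of the feature value
#'
#' Returns the running segment mean of the features observed since the last
#' reset — the degenerate (zero-trend) AR prediction.
#'
#' @param state An `anomaly_state` with at least one observation.
#' @return Scalar prediction.
#' @export
predict_feature <- function(state) {
  if (state$count == 0L) {
    stop("No observations in segment: cannot predict before the first feature.",
         call. = FALSE)
  }
  state$q_bar
}

#' Absolute prediction error
#'
#' Euclidean distance in one dimension between the observed and predicted
#' feature value.
#'
#' @param q_t Observed feature value.
#' @param q_hat Predicted feature value.
#' @return `|q_t - q_hat|`.
#' @export
prediction_error <- function(q_t, q_hat) {
  stopifnot(is.finite(q_t), is.finite(q_hat))
  abs(q_t - q_hat)
}

#' Standardize an error against the running segment statistics
#'
#' `z_t = (e_t - e_mean) / max(e_sd, epsilon)` with `e_mean`, `e_sd` the
#' running mean and standard deviation of errors observed earlier in the
#' segment; the first error after a reset standardizes to 0 (no prior
#' statistics). The error is folded into the running statistics afterwards.
#'
#' @param state An `anomaly_state`.
#' @param e_t Non-negative error.
#' @return `list(z = <standardized residual>, state = <updated state>)`.
#' @export
standardize_error <- function(state, e_t) {
  e_sd <- if (state$e_count >= 2L) sqrt(state$e_m2 / state$e_count) else 0
  if (state$e_count == 0L || e_sd == 0) {
    # no prior errors, or a zero-spread history: standardization is
    # undefined, emit the warm-up value (dividing by the epsilon floor here
    # would inject an astronomically large residual into the running mean H
    # and swamp every later score)
    z <- if (state$e_count > 0L && e_t != state$e_mean && e_sd == 0 &&
             state$e_count >= 2L) (e_t - state$e_mean) / state$epsilon else 0
  } else {
    z <- (e_t - state$e_mean) / max(e_sd, state$epsilon)
  }
  # Welford update (population variance over the segment history)
  state$e_count <- state$e_count + 1L
  d <- e_t - state$e_mean
  state$e_mean <- state$e_mean + d / state$e_count
  state$e_m2 <- state$e_m2 + d * (e_t - state$e_mean)
  list(z = z, state = state)
}

#' Strangeness score of a standardized residual
#'
#' `s_t = |z_t - H|` with `H` the running mean of the previous residuals in
#' the segment; the first residual after a reset scores 0. `z_t` is folded
#' into `H` afterwards.
#'
#' @param state An `anomaly_state`.
#' @param z_t Standardized residual.
#' @return `list(s = <score>, state = <updated state>)`.
#' @export
anomaly_score <- function(state, z_t) {
  s <- if (state$z_count == 0L) 0 else abs(z_t - state$H)
  state$z_count <- state$z_count + 1L
  state$H <- state$H + (z_t - state$H) / state$z_count
  list(s = s, state = state)
}

# Advance the state by one feature value; returns list(e, z, s, state).
observe_feature <- function(state, q_t) {
  if (state$count == 0L) {
    e <- 0  # no prediction before the first observation
  } else {
    e <- prediction_error(q_t, predict_feature(state))
  }
  state$count <- state$count + 1L
  state$q_bar <- state$q_bar + (q_t - state$q_bar) / state$count
  sz <- standardize_error(state, e)
  sc <- anomaly_score(sz$state, sz$z)
  list(e = e, z = sz$z, s = sc$s, state = sc$state)
}

#' Score a feature series
#'
#' Runs the full causal chain (predict, error, standardize, strangeness) over
#' a feature series in a single online pass, with no resets. Used directly for
#' diagnostics and by [detect_changes()] (which additionally resets the state
#' after each declared change).
#'
#' @param features A tibble with columns `index`, `q` (from
#'   [extract_features()]) or a numeric vector of feature values.
#' @param epsilon Zero-variance guard (default `1e-8`).
#' @param standardization `"online"` (causal running statistics; default) or
#'   `"batch"` (whole-series mean/sd — retrospective, for comparison only;
#'   breaks the real-time contract).
#' @return A tibble with columns `index`, `q`, `e`, `z`, `s`.
#' @export
score_stream <- function(features, epsilon = 1e-8,
                         standardization = c("online", "batch")) {
  standardization <- match.arg(standardization)
  if (is.data.frame(features)) {
    q <- features$q
    index <- features$index
  } else {
    q <- as.numeric(features)
    index <- seq_along(q) - 1L
  }
  n <- length(q)
  if (n == 0) stop("Feature series is empty.", call. = FALSE)

  if (standardization == "batch") {
    q_bar_run <- cumsum(q) / seq_len(n)
    e <- c(0, abs(q[-1] - q_bar_run[-n]))
    e_sd <- stats::sd(e) * sqrt((n - 1) / n)
    z <- (e - mean(e)) / max(e_sd, epsilon)
    if (n == 1) z <- 0
    H_prev <- c(0, cumsum(z)[-n] / seq_len(n - 1))
    s <- abs(z - H_prev)
    s[1] <- 0
    return(tibble::tibble(index = index, q = q, e = e, z = z, s = s))
  }

  state <- new_anomaly_state(epsilon)
  e <- z <- s <- numeric(n)
  for (t in seq_len(n)) {
    step <- observe_feature(state, q[t])
    e[t] <- step$e; z[t] <- step$z; s[t] <- step$s
    state <- step$state
  }
  tibble::tibble(index = index, q = q, e = e, z = z, s = s)
}
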
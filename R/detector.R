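#' Detect change points in a signal stream
#'
#' Runs the full online pipeline in a single causal pass:
#' joint-entropy features over a sliding window, anomaly scores from the
#' zero-trend AR residual chain, and the Randomized Power Martingale test.
#' When the martingale reaches `lambda` (and at least `burn_in` scores have
#' elapsed since the last reset) the current time is declared a change; the
#' martingale is then reset to 1 and the segment statistics (score history,
#' running residual statistics) restart, so post-change data is judged
#' against a fresh baseline. The pass continues to the end of the stream, so
#' several changes can be found.
#'
#' The reported change time is the *detection* time — the first index at
#' which the martingale crosses the threshold — in three coordinate systems:
#' score index (0-based over emitted scores), decimated-sample index (score
#' index plus the `L - 1` window warm-up), and original-sample index
#' (undoing decimation).
#'
#' @param stream A [signal_stream()].
#' @param lambda Decision threshold (> 1; default 3, a balanced
#'   precision/recall operating point). Larger values detect fewer, more
#'   conservative changes; the false-alarm probability per segment is bounded
#'   by `1 / lambda` (Doob's maximal inequality).
#' @param L Sliding-window length in samples (default 5).
#' @param xi Martingale power parameter in `(0, 1)` (default 0.8).
#' @param burn_in Minimum number of scores after a reset before an alarm may
#'   fire (default 10); guards against spurious crossings on the first few
#'   p-values of a segment.
#' @param decimate Down-sampling factor applied before feature extraction
#'   (default 1; use 50 for 512 Hz EEG streams).
#' @param epsilon Zero-variance guard for residual standardization.
#' @param seed Integer seed for the tie-breaking randomization; if `NULL` the
#'   current RNG state is used. Identical stream + config + seed gives an
#'   identical result.
#'
#' @return An object of class `change_detection`: a list with elements
#'   `changes` (tibble: `stream_id`, `score_index`, `decimated_index`,
#'   `original_index`, `martingale_value`), `trace` (per-score tibble:
#'   `score_index`, `decimated_index`, `q`, `e`, `z`, `s`, `p_hat`, `M`,
#'   `segment`), and `config`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' str <- gen_concatenated_stream(
#'   segment_spec(2048, "ar2-oscillator"),
#'   segment_spec(2048, "ar2-oscillator", amplitude_scale = 5),
#'   seed = 1
#' )
#' fit <- detect_changes(decimate_stream(str$stream, 10), lambda = 3, seed = 1)
#' tidy(fit)
detect_changes <- function(stream, lambda = 3, L = 5L, xi = 0.8,
                           burn_in = 10L, decimate = 1L, epsilon = 1e-8,
                           seed = NULL) {
  stopifnot(inherits(stream, "signal_stream"))
  if (!is.numeric(lambda) || lambda <= 1) {
    stop("`lambda` must be > 1.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (decimate > 1L) stream <- decimate_stream(stream, decimate)
  if (nrow(stream) < L + 2L) {
    stop(sprintf("Stream too short (%d samples) for window length %d.",
                 nrow(stream), L), call. = FALSE)
  }

  feats <- extract_features(stream, L = L)
  q <- feats$q
  n <- length(q)

  a_state <- new_anomaly_state(epsilon)
  m_state <- new_martingale_state(xi)
  seg <- 1L
  seg_scores <- 0L

  e <- z <- s <- p_hat <- M <- numeric(n)
  segment <- integer(n)
  ch_score_index <- integer(0)
  ch_M <- numeric(0)

  for (t in seq_len(n)) {
    step <- observe_feature(a_state, q[t])
    a_state <- step$state
    e[t] <- step$e; z[t] <- step$z; s[t] <- step$s

    upd <- martingale_update(m_state, step$s)
    m_state <- upd$state
    p_hat[t] <- upd$p_hat
    M[t] <- upd$M
    segment[t] <- seg
    seg_scores <- seg_scores + 1L

    if (upd$M >= lambda && seg_scores >= burn_in) {
      ch_score_index <- c(ch_score_index, t - 1L)
      ch_M <- c(ch_M, upd$M)
      a_state <- reset_anomaly_state(a_state)
      m_state <- new_martingale_state(xi)
      seg <- seg + 1L
      seg_scores <- 0L
    }
  }

  dfac <- decimation_factor(stream)
  off <- origin_offset(stream)
  dec_index <- ch_score_index + (L - 1L)
  changes <- tibble::tibble(
    stream_id = stream_id(stream),
    score_index = ch_score_index,
    decimated_index = dec_index,
    original_index = dec_index * dfac + off,
    martingale_value = ch_M
  )
  trace <- tibble::tibble(
    score_index = seq_len(n) - 1L,
    decimated_index = feats$index,
    q = q, e = e, z = z, s = s, p_hat = p_hat, M = M, segment = segment
  )
  structure(
    list(
      changes = changes,
      trace = trace,
      config = list(lambda = lambda, L = L, xi = xi, burn_in = burn_in,
                    epsilon = epsilon, seed = seed,
                    decimation_factor = dfac, origin_offset = off,
                    sampling_rate = sampling_rate(stream)),
      stream_id = stream_id(stream),
      n_scores = n
    ),
    class = "change_detection"
  )
}

#' @export
print.change_detection <- function(x, ...) {
  cat(sprintf(
    "<change_detection '%s'> %d change(s) over %d scores (lambda = %g, xi = %g, L = %d)\n",
    x$stream_id, nrow(x$changes), x$n_scores,
    x$config$lambda, x$config$xi, x$config$L
  ))
  if (nrow(x$changes) > 0) print(x$changes)
  invisible(x)
}

#' Tidy a change-detection result
#'
#' @param x A `change_detection` object.
#' @param ... Unused.
#' @return The detections tibble (one row per declared change).
#' @method tidy change_detection
#' @export
tidy.change_detection <- function(x, ...) x$changes

#' One-row summary of a change-detection result
#'
#' @param x A `change_detection` object.
#' @param ... Unused.
#' @return One-row tibble: `stream_id`, `n_changes`, `n_scores`, `lambda`,
#'   `xi`, `L`, `burn_in`, `max_martingale`.
#' @method glance change_detection
#' @export
glance.change_detection <- function(x, ...) {
  tibble::tibble(
    stream_id = x$stream_id,
    n_changes = nrow(x$changes),
    n_scores = x$n_scores,
    lambda = x$config$lambda,
    xi = x$config$xi,
    L = x$config$L,
    burn_in = x$config$burn_in,
    max_martingale = max(x$trace$M)
  )
}

#' Sweep the decision threshold over a labelled corpus
#'
#' Runs [detect_changes()] at each threshold in `lambda_grid` over a corpus of
#' streams with known change points and evaluates pooled precision, recall and
#' F-score. Each stream gets a deterministic per-stream seed derived from
#' `seed`, shared across thresholds, so the threshold is the only thing that
#' varies along the grid.
#'
#' @param streams A list of [signal_stream()] objects (or a single stream).
#' @param truth Ground-truth tibble (`stream_id`, `change_index`), indices in
#'   decimated coordinates.
#' @param lambda_grid Thresholds to evaluate (default `seq(2, 9, by = 0.5)`).
#' @param tolerance Matching tolerance in decimated samples (default 20).
#' @param seed Base integer seed.
#' @param ... Further arguments to [detect_changes()] (e.g. `L`, `xi`,
#'   `burn_in`, `decimate`).
#'
#' @return Tibble with one row per threshold: `lambda`, `N`, `N_g`, `n_m`,
#'   `precision`, `recall`, `f_score`.
#' @export
lambda_sweep <- function(streams, truth, lambda_grid = seq(2, 9, by = 0.5),
                         tolerance = 20L, seed = 1L, ...) {
  if (inherits(streams, "signal_stream")) streams <- list(streams)
  if (length(lambda_grid) == 0) stop("`lambda_grid` is empty.", call. = FALSE)
  ids <- vapply(streams, stream_id, character(1))
  missing <- setdiff(ids, unique(truth$stream_id))
  if (length(missing) > 0) {
    stop("No ground truth for stream(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(lambda_grid, function(lam) {
    det <- purrr::imap_dfr(streams, function(st, i) {
      tidy(detect_changes(st, lambda = lam, seed = seed + i - 1L, ...))
    })
    ev <- evaluate_detections(det, truth, tolerance = tolerance)
    pooled <- ev[ev$stream_id == "(pooled)", ]
    tibble::tibble(
      lambda = lam, N = pooled$N, N_g = pooled$N_g, n_m = pooled$n_m,
      precision = pooled$precision, recall = pooled$recall,
      f_score = pooled$f_score
    )
  })
}
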
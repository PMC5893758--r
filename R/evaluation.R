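#' Match detected change points to ground truth
#'
#' Greedy one-to-one matching in increasing truth order: each truth index
#' consumes the earliest still-unmatched detection within `+-tolerance`.
#' Because the feasibility sets are intervals on a line, this greedy attains
#' the maximum possible number of one-to-one pairs (the standard exchange
#' argument for interval matching), so the count equals what exhaustive
#' assignment would find. It is at most `min(length(detected),
#' length(truth))` and never decreases as the tolerance grows.
#'
#' @param detected Sorted non-negative detection indices.
#' @param truth Sorted non-negative ground-truth indices.
#' @param tolerance Non-negative matching window, in the same (decimated)
#'   sample units as the indices.
#' @return Integer: number of matched detections `n_m`.
#' @export
#' @examples
#' match_changes(c(98, 350), c(100, 200, 300), tolerance = 10)  # 1
match_changes <- function(detected, truth, tolerance) {
  if (is.unsorted(detected) || is.unsorted(truth)) {
    stop("`detected` and `truth` must be sorted increasingly.", call. = FALSE)
  }
  stopifnot(tolerance >= 0)
  n_m <- 0L
  j <- 1L
  for (g in truth) {
    while (j <= length(detected) && detected[j] < g - tolerance) j <- j + 1L
    if (j <= length(detected) && detected[j] <= g + tolerance) {
      n_m <- n_m + 1L
      j <- j + 1L
    }
  }
  n_m
}

#' Precision, recall and F-score from match counts
#'
#' `precision = n_m / N` (fraction of detections that match a labelled
#' change), `recall = n_m / N_g` (fraction of labelled changes recovered),
#' `f_score` their harmonic mean. Zero denominators yield 0 by convention.
#'
#' @param N Number of detections.
#' @param N_g Number of ground-truth changes.
#' @param n_m Number of matched detections (`<= min(N, N_g)`).
#' @return One-row tibble: `N`, `N_g`, `n_m`, `precision`, `recall`,
#'   `f_score`.
#' @export
#' @examples
#' compute_metrics(4, 5, 3)
compute_metrics <- function(N, N_g, n_m) {
  if (n_m > min(N, N_g)) {
    stop("`n_m` cannot exceed min(N, N_g).", call. = FALSE)
  }
  precision <- if (N > 0) n_m / N else 0
  recall <- if (N_g > 0) n_m / N_g else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(N = N, N_g = N_g, n_m = n_m,
                 precision = precision, recall = recall, f_score = f)
}

#' Evaluate detections against ground truth, per stream and pooled
#'
#' Matches per stream with [match_changes()] and reports one metrics row per
#' stream plus a pooled row (id `"(pooled)"`). Pooling sums `N`, `N_g`, `n_m`
#' across streams and applies the metric formulas to the sums; set
#' `pooled = "macro"` to average the per-stream metrics instead.
#'
#' @param detections Tibble with columns `stream_id` and `decimated_index`
#'   (as written by [write_detections()] / produced by [tidy()] on a
#'   detection result).
#' @param truth Tibble with columns `stream_id`, `change_index`.
#' @param tolerance Matching window in decimated samples (default 20; about
#'   2 s for 512 Hz recordings decimated 1:50).
#' @param pooled `"micro"` (sums, default) or `"macro"` (mean of per-stream
#'   metrics) for the summary row.
#' @return Tibble: one row per stream plus the `"(pooled)"` row, columns
#'   `stream_id`, `N`, `N_g`, `n_m`, `precision`, `recall`, `f_score`.
#' @export
evaluate_detections <- function(detections, truth, tolerance = 20L,
                                pooled = c("micro", "macro")) {
  pooled <- match.arg(pooled)
  ids <- sort(unique(c(detections$stream_id, truth$stream_id)))
  per <- purrr::map_dfr(ids, function(id) {
    det <- sort(detections$decimated_index[detections$stream_id == id])
    tru <- sort(truth$change_index[truth$stream_id == id])
    n_m <- match_changes(det, tru, tolerance)
    dplyr::bind_cols(tibble::tibble(stream_id = id),
                     compute_metrics(length(det), length(tru), n_m))
  })
  pool <- if (pooled == "micro") {
    dplyr::bind_cols(
      tibble::tibble(stream_id = "(pooled)"),
      compute_metrics(sum(per$N), sum(per$N_g), sum(per$n_m))
    )
  } else {
    tibble::tibble(
      stream_id = "(pooled)",
      N = sum(per$N), N_g = sum(per$N_g), n_m = sum(per$n_m),
      precision = mean(per$precision), recall = mean(per$recall),
      f_score = mean(per$f_score)
    )
  }
  dplyr::bind_rows(per, pool)
}
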
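#' Time-domain features of one sliding window
#'
#' Five amplitude statistics of a length-`L` window: mean, maximum, minimum,
#' population variance (1/L normalization) and its square root. Together they
#' summarize the local amplitude behaviour of the signal; they are combined
#' into a single scalar by [joint_entropy()].
#'
#' @param window Numeric vector of length `L >= 2`, all finite.
#' @return A named numeric vector `c(f1, f2, f3, f4, f5)`.
#' @export
#' @examples
#' window_features(c(1, 2, 3, 4, 5))
window_features <- function(window) {
  if (length(window) < 2) {
    stop("Window must contain at least 2 samples.", call. = FALSE)
  }
  if (!all(is.finite(window))) {
    stop("Window values must be finite.", call. = FALSE)
  }
  f1 <- mean(window)
  f4 <- mean((window - f1)^2)  # population variance, 1/L
  c(f1 = f1, f2 = max(window), f3 = min(window), f4 = f4, f5 = sqrt(f4))
}

#' Joint entropy of a feature vector
#'
#' Collapses the five window statistics into one scalar: the Shannon entropy
#' (natural log, sign convention of sum p*log p, hence non-positive) of the
#' L1-normalized absolute feature magnitudes. EEG amplitudes oscillate around
#' zero, so raw means and minima are routinely negative; taking absolute
#' magnitudes and normalizing makes the combination well defined while
#' preserving what the scalar is for — a summary of the *relative* sizes of
#' the window statistics that tracks amplitude fluctuation. Because the
#' variance enters quadratically in amplitude while the other four statistics
#' enter linearly, the value shifts when the local amplitude scale changes.
#'
#' Conventions: if all features are zero the result is 0; terms with
#' `p_j = 0` contribute 0 (`0 * log 0 = 0`, with an `epsilon` floor guarding
#' `log`). The result always lies in `[-log(5), 0]`.
#'
#' @param fv Numeric vector of 5 features (as from [window_features()]).
#' @param epsilon Floor inside the logarithm (default `1e-12`).
#' @return Scalar in `[-log(5), 0]`.
#' @export
#' @examples
#' joint_entropy(window_features(c(1, 2, 3, 4, 5)))
joint_entropy <- function(fv, epsilon = 1e-12) {
  a <- abs(as.numeric(fv))
  s <- sum(a)
  if (s == 0) return(0)
  p <- a / s
  sum(ifelse(p > 0, p * log(pmax(p, epsilon)), 0))
}

#' Extract the joint-entropy feature series of a stream
#'
#' Slides a window of length `L` over the stream; for each sample index
#' `k >= L - 1` (0-based) the window `samples[(k - L + 1):k]` yields a feature
#' vector whose joint entropy is the feature value `q` at `k`. The output has
#' `N - L + 1` rows: the first `L - 1` samples have no full window.
#'
#' @param stream A [signal_stream()] (or a data frame with an `amplitude`
#'   column) of length at least `L`.
#' @param L Window length (default 5).
#' @param epsilon Passed to [joint_entropy()].
#' @return A tibble with columns `index` (decimated-sample index of the window
#'   end) and `q`; attributes `window_length` and `start_index = L - 1`.
#' @export
#' @examples
#' s <- signal_stream(rnorm(205), sampling_rate = 10.24)
#' extract_features(s, L = 5)  # 201 rows
extract_features <- function(stream, L = 5L, epsilon = 1e-12) {
  x <- if (is.data.frame(stream)) stream$amplitude else as.numeric(stream)
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("`L` must be an integer >= 2.", call. = FALSE)
  n <- length(x)
  if (n < L) {
    stop(sprintf("Stream has %d samples; window length %d requires at least %d.",
                 n, L, L), call. = FALSE)
  }
  # rolling statistics, vectorized over window starts
  n_win <- n - L + 1L
  idx <- seq_len(n_win)
  csum <- cumsum(c(0, x))
  csum2 <- cumsum(c(0, x^2))
  f1 <- (csum[idx + L] - csum[idx]) / L
  f4 <- (csum2[idx + L] - csum2[idx]) / L - f1^2
  f4 <- pmax(f4, 0)  # clamp negative rounding error
  f2 <- vapply(idx, function(i) max(x[i:(i + L - 1L)]), numeric(1))
  f3 <- vapply(idx, function(i) min(x[i:(i + L - 1L)]), numeric(1))
  f5 <- sqrt(f4)

  a <- abs(cbind(f1, f2, f3, f4, f5))
  s <- rowSums(a)
  p <- a / ifelse(s == 0, 1, s)
  q <- rowSums(ifelse(p > 0, p * log(pmax(p, epsilon)), 0))
  q[s == 0] <- 0

  out <- tibble::tibble(index = (idx - 1L) + (L - 1L), q = q)
  attr(out, "window_length") <- L
  attr(out, "start_index") <- L - 1L
  out
}
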
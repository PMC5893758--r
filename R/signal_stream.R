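#' Construct a signal stream
#'
#' A signal stream is a tibble with one row per retained sample and columns
#' `index` (0-based position in the *current*, possibly decimated, stream) and
#' `amplitude`. Provenance metadata — sampling rate, decimation factor and the
#' offset of sample 0 in the pre-decimation recording — travels as attributes
#' so that detections can always be mapped back to raw-sample coordinates.
#'
#' @param samples Numeric vector of finite amplitudes (microvolt-scale for EEG,
#'   but units are arbitrary).
#' @param sampling_rate Sampling rate in Hz of *these* samples (after any
#'   decimation already applied). Must be positive.
#' @param stream_id Character scalar identifying the stream.
#' @param decimation_factor Positive integer; 1 means the raw recording.
#' @param origin_offset Non-negative integer: index, in the pre-decimation
#'   recording, of sample 0.
#'
#' @return A tibble of class `signal_stream` with columns `index`, `amplitude`.
#' @export
#' @examples
#' s <- signal_stream(sin(seq_len(100) / 5), sampling_rate = 512)
#' s
signal_stream <- function(samples, sampling_rate = 512, stream_id = "stream",
                          decimation_factor = 1L, origin_offset = 0L) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) {
    stop("`samples` must be non-empty.", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf).", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive scalar.", call. = FALSE)
  }
  decimation_factor <- as.integer(decimation_factor)
  origin_offset <- as.integer(origin_offset)
  if (is.na(decimation_factor) || decimation_factor < 1L) {
    stop("`decimation_factor` must be a positive integer.", call. = FALSE)
  }
  if (is.na(origin_offset) || origin_offset < 0L) {
    stop("`origin_offset` must be a non-negative integer.", call. = FALSE)
  }
  out <- tibble::tibble(index = seq_along(samples) - 1L, amplitude = samples)
  structure(
    out,
    class = c("signal_stream", class(out)),
    sampling_rate = sampling_rate,
    stream_id = as.character(stream_id),
    decimation_factor = decimation_factor,
    origin_offset = origin_offset
  )
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf(
    "<signal_stream '%s'> %d samples @ %g Hz (decimation 1:%d, origin offset %d)\n",
    stream_id(x), nrow(x), sampling_rate(x), decimation_factor(x),
    attr(x, "origin_offset")
  ))
  NextMethod()
}

#' Stream metadata accessors
#'
#' @param stream A [signal_stream()].
#' @return Scalar metadata value.
#' @export
sampling_rate <- function(stream) attr(stream, "sampling_rate")

#' @rdname sampling_rate
#' @export
stream_id <- function(stream) attr(stream, "stream_id")

#' @rdname sampling_rate
#' @export
decimation_factor <- function(stream) attr(stream, "decimation_factor")

#' @rdname sampling_rate
#' @export
origin_offset <- function(stream) attr(stream, "origin_offset")

#' Down-sample a stream by plain sample-picking
#'
#' Keeps samples at positions 0, `factor`, 2·`factor`, … of the input. No
#' anti-alias filter is applied by default: downstream feature extraction
#' summarizes amplitude statistics, for which decimation is simply a thinning
#' of the record. An optional moving-average pre-filter is available for users
#' who want to suppress aliasing of narrow-band rhythms.
#'
#' @param stream A [signal_stream()].
#' @param factor Positive integer down-sampling factor (1 returns the input).
#' @param antialias If `TRUE`, apply a length-`factor` centered moving average
#'   before picking samples. Default `FALSE`.
#'
#' @return A [signal_stream()] of length `ceiling(n / factor)` with
#'   `sampling_rate / factor` and an updated `decimation_factor`.
#' @export
#' @examples
#' s <- signal_stream(rnorm(10240), sampling_rate = 512)
#' decimate_stream(s, 50)  # 205 samples at 10.24 Hz
decimate_stream <- function(stream, factor, antialias = FALSE) {
  stopifnot(inherits(stream, "signal_stream"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("`factor` must be a positive integer.", call. = FALSE)
  }
  x <- stream$amplitude
  if (factor == 1L) return(stream)
  if (antialias) {
    sm <- stats::filter(x, rep(1 / factor, factor), sides = 2)
    x <- ifelse(is.na(sm), x, as.numeric(sm))
  }
  keep <- seq.int(1L, length(x), by = factor)
  signal_stream(
    x[keep],
    sampling_rate = sampling_rate(stream) / factor,
    stream_id = stream_id(stream),
    decimation_factor = decimation_factor(stream) * factor,
    origin_offset = origin_offset(stream)
  )
}
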
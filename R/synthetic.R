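#' Specify a synthetic signal segment
#'
#' Defines one statistically homogeneous stretch of a synthetic stream.
#' Two generating processes are available:
#' * `"iid-gaussian"` — white noise; the exchangeable null for calibration
#'   studies.
#' * `"ar2-oscillator"` — a stationary AR(2) process whose complex
#'   characteristic roots produce a damped band-limited rhythm, a simple
#'   surrogate for ongoing EEG background activity (no claim of
#'   physiological fidelity — see the package vignette).
#'
#' The default AR coefficients place the spectral peak near 10 Hz for a
#' 512 Hz sampling rate with pole modulus 0.95.
#'
#' @param length Segment length in samples.
#' @param process `"iid-gaussian"` or `"ar2-oscillator"`.
#' @param mean Additive level (default 0; EEG oscillates around zero).
#' @param amplitude_scale Multiplicative amplitude (default 1). Raising it
#'   (and/or `noise_sd`) makes a segment "focal-like": same rhythm, larger
#'   excursions.
#' @param ar Length-2 AR coefficients; the process must be stationary (roots
#'   of `1 - a1 z - a2 z^2` outside the unit circle).
#' @param noise_sd Innovation standard deviation (default 1).
#' @return A `segment_spec` list.
#' @export
segment_spec <- function(length, process = c("iid-gaussian", "ar2-oscillator"),
                         mean = 0, amplitude_scale = 1,
                         ar = c(2 * 0.95 * cos(2 * pi * 10 / 512), -0.95^2),
                         noise_sd = 1) {
  process <- match.arg(process)
  stopifnot(length >= 1, amplitude_scale > 0, noise_sd > 0)
  if (process == "ar2-oscillator") {
    stopifnot(base::length(ar) == 2)
    roots <- polyroot(c(1, -ar[1], -ar[2]))
    if (any(Mod(roots) <= 1)) {
      stop("AR(2) coefficients are non-stationary (characteristic root on or inside the unit circle).",
           call. = FALSE)
    }
  }
  structure(
    list(length = as.integer(length), process = process, mean = mean,
         amplitude_scale = amplitude_scale, ar = ar, noise_sd = noise_sd),
    class = "segment_spec"
  )
}

# Raw samples for one segment (RNG state is the caller's responsibility).
gen_segment <- function(spec) {
  x <- switch(spec$process,
    "iid-gaussian" = stats::rnorm(spec$length, sd = spec$noise_sd),
    "ar2-oscillator" = as.numeric(stats::arima.sim(
      model = list(ar = spec$ar), n = spec$length, sd = spec$noise_sd
    ))
  )
  spec$mean + spec$amplitude_scale * x
}

#' Generate a homogeneous (null) stream
#'
#' One segment with no change point; reproducible under `seed`.
#'
#' @param n Number of samples.
#' @param spec A [segment_spec()] (its `length` is overridden by `n`).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param sampling_rate Sampling rate recorded on the stream (default 512).
#' @param stream_id Stream identifier.
#' @return A [signal_stream()].
#' @export
gen_null_stream <- function(n, spec = segment_spec(n), seed = NULL,
                            sampling_rate = 512, stream_id = "null") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  spec$length <- as.integer(n)
  signal_stream(gen_segment(spec), sampling_rate = sampling_rate,
                stream_id = stream_id)
}

#' Generate a two-segment stream with one known change point
#'
#' Concatenates a draw from `spec_a` and a draw from `spec_b`; the ground
#' truth change index is the length of the first segment (0-based index of
#' the first sample of segment B), in the coordinates of the returned raw
#' stream. If the stream is decimated downstream by factor `d`, the change
#' index becomes `ceiling(length_a / d)`.
#'
#' @param spec_a,spec_b [segment_spec()]s for the two segments. They should
#'   differ in amplitude and/or noise level; identical specs trigger a
#'   warning (the change is undetectable by construction).
#' @param seed Integer seed.
#' @param sampling_rate Sampling rate recorded on the stream.
#' @param stream_id Stream identifier.
#' @return `list(stream = <signal_stream>, truth = <tibble stream_id,
#'   change_index>)`.
#' @export
gen_concatenated_stream <- function(spec_a, spec_b, seed = NULL,
                                    sampling_rate = 512,
                                    stream_id = "concat") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (identical(spec_a[c("process", "mean", "amplitude_scale", "ar", "noise_sd")],
                spec_b[c("process", "mean", "amplitude_scale", "ar", "noise_sd")])) {
    warning("Segment specs are identical: the change point is undetectable by construction.")
  }
  x <- c(gen_segment(spec_a), gen_segment(spec_b))
  list(
    stream = signal_stream(x, sampling_rate = sampling_rate,
                           stream_id = stream_id),
    truth = tibble::tibble(stream_id = stream_id,
                           change_index = spec_a$length)
  )
}

#' I.i.d. null anomaly scores
#'
#' Absolute standard-normal draws: continuous, non-negative, exchangeable —
#' a direct input for martingale calibration studies that bypasses the
#' signal front end.
#'
#' @param n Number of scores.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, all `>= 0`.
#' @export
gen_score_null <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  abs(stats::rnorm(n))
}

#' Generate a labelled synthetic corpus of two-segment streams
#'
#' The `"bern-like"` preset mirrors the construction used for focal /
#' non-focal EEG benchmarking: each stream concatenates two 20 s segments at
#' 512 Hz (10,240 samples each) — a baseline AR(2) oscillation followed by
#' the same rhythm at `amplitude_ratio` times the amplitude — then decimates
#' 1:50, leaving 205 + 205 samples with the change at decimated index 205.
#'
#' @param n_streams Number of streams (default 50).
#' @param seed Base integer seed; stream `i` uses `seed + i - 1`.
#' @param preset Currently only `"bern-like"`.
#' @param segment_seconds Duration of each segment (default 20).
#' @param sampling_rate Raw sampling rate in Hz (default 512).
#' @param decimate Down-sampling factor (default 50).
#' @param amplitude_ratio Amplitude of segment B relative to A (default 5).
#' @return `list(streams = <list of decimated signal_streams>,
#'   truth = <tibble stream_id, change_index>)`.
#' @export
simulate_corpus <- function(n_streams = 50L, seed = 1L, preset = "bern-like",
                            segment_seconds = 20, sampling_rate = 512,
                            decimate = 50L, amplitude_ratio = 5) {
  preset <- match.arg(preset, "bern-like")
  n_seg <- as.integer(round(segment_seconds * sampling_rate))
  streams <- vector("list", n_streams)
  truth <- vector("list", n_streams)
  for (i in seq_len(n_streams)) {
    id <- sprintf("sim%04d", i)
    spec_a <- segment_spec(n_seg, "ar2-oscillator")
    spec_b <- segment_spec(n_seg, "ar2-oscillator",
                           amplitude_scale = amplitude_ratio)
    g <- gen_concatenated_stream(spec_a, spec_b, seed = seed + i - 1L,
                                 sampling_rate = sampling_rate,
                                 stream_id = id)
    dec <- decimate_stream(g$stream, decimate)
    streams[[i]] <- dec
    truth[[i]] <- tibble::tibble(
      stream_id = id,
      change_index = as.integer(ceiling(n_seg / decimate))
    )
  }
  list(streams = streams, truth = dplyr::bind_rows(truth))
}
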
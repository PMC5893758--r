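#' Read a signal stream from a plain-text / CSV file
#'
#' Supported dialects:
#' * `"bern-barcelona"` — two comma-separated numeric columns per row
#'   (simultaneous x/y channel pair); the first column (the x-signal) is used
#'   unless `column` says otherwise. Default sampling rate 512 Hz.
#' * `"single-column"` — one numeric value per line.
#' * `"csv"` — general delimited text; pick `column`.
#'
#' The delimiter is auto-detected (comma, then whitespace) unless `delim` is
#' given. One leading header line is tolerated and skipped if it is not
#' numeric. Rows must all have the requested column and be numeric; a
#' violation reports the offending line.
#'
#' @param path File to read.
#' @param dialect One of `"bern-barcelona"`, `"single-column"`, `"csv"`.
#' @param column 1-based column to extract (default 1).
#' @param sampling_rate Sampling rate in Hz of the stored samples (default 512,
#'   the rate of the focal/non-focal EEG recordings this reader targets).
#' @param stream_id Stream identifier; defaults to the file name sans extension.
#' @param delim Optional delimiter override (e.g. `","`).
#'
#' @return A [signal_stream()] with `decimation_factor = 1`, `origin_offset = 0`.
#' @export
read_signal <- function(path,
                        dialect = c("bern-barcelona", "single-column", "csv"),
                        column = 1L,
                        sampling_rate = 512,
                        stream_id = NULL,
                        delim = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("Signal file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop(sprintf("Signal file is empty: '%s'", path), call. = FALSE)
  }
  if (is.null(delim)) {
    delim <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else "[[:space:]]+"
  }
  split_row <- function(line) strsplit(trimws(line), delim)[[1]]

  first_fields <- split_row(lines[[1]])
  skip_header <- any(is.na(suppressWarnings(as.numeric(first_fields))))
  if (skip_header) {
    lines <- lines[-1]
    if (length(lines) == 0) {
      stop(sprintf("Signal file has a header but no data: '%s'", path),
           call. = FALSE)
    }
  }

  column <- as.integer(column)
  n_expect <- if (dialect == "single-column") 1L else NA_integer_
  values <- numeric(length(lines))
  for (i in seq_along(lines)) {
    fields <- split_row(lines[[i]])
    if (!is.na(n_expect) && length(fields) != n_expect) {
      stop(sprintf("Line %d of '%s': expected %d field(s), found %d.",
                   i + skip_header, path, n_expect, length(fields)),
           call. = FALSE)
    }
    if (length(fields) < column) {
      stop(sprintf("Line %d of '%s': column %d missing (row has %d fields).",
                   i + skip_header, path, column, length(fields)),
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(fields[[column]]))
    if (is.na(v)) {
      stop(sprintf("Line %d of '%s': non-numeric value '%s'.",
                   i + skip_header, path, fields[[column]]), call. = FALSE)
    }
    values[[i]] <- v
  }

  if (is.null(stream_id)) {
    stream_id <- sub("\\.[^.]*$", "", basename(path))
  }
  signal_stream(values, sampling_rate = sampling_rate, stream_id = stream_id)
}

#' Write / read detected change points as CSV
#'
#' The detections table carries, per change, the stream id, the index in the
#' decimated stream, the reconstructed index in the original recording
#' (`decimated_index * decimation_factor + origin_offset`, exact integer
#' arithmetic) and the martingale value at detection. Round-trips losslessly
#' through [read_detections()].
#'
#' @param detections A tibble with columns `stream_id`, `decimated_index`,
#'   `original_index`, `martingale_value` (as produced by [detect_changes()]
#'   via [generics::tidy()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  cols <- c("stream_id", "decimated_index", "original_index", "martingale_value")
  missing <- setdiff(cols, names(detections))
  if (length(missing) > 0) {
    stop("Detections table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(detections[, cols, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      stream_id = readr::col_character(),
      decimated_index = readr::col_integer(),
      original_index = readr::col_integer(),
      martingale_value = readr::col_double()
    )
  )
}

#' Write / read ground-truth change lists as CSV
#'
#' Ground truth is a tibble with columns `stream_id` and `change_index`
#' (indices into the decimated stream, 0-based, strictly increasing per
#' stream).
#'
#' @param truth Ground-truth tibble.
#' @param path CSV path.
#' @return `path`, invisibly (writer); the tibble (reader).
#' @export
write_ground_truth <- function(truth, path) {
  cols <- c("stream_id", "change_index")
  missing <- setdiff(cols, names(truth))
  if (length(missing) > 0) {
    stop("Ground-truth table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(truth[, cols, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      stream_id = readr::col_character(),
      change_index = readr::col_integer()
    )
  )
}
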
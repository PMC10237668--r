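#' Construct an f0 contour
#'
#' A contour is a sampled fundamental-frequency trajectory: a strictly
#' increasing time axis in milliseconds and f0 values in semitones relative to
#' a reference frequency (by convention the speaker's median f0; see
#' [hz_to_semitones()]).
#'
#' @param times Numeric vector of sample times in milliseconds, strictly
#'   increasing, at least two samples.
#' @param values Numeric vector of f0 values in semitones, same length as
#'   `times`, all finite.
#' @param label Optional free-text label (token id, condition).
#' @return An object of class `contour` with fields `times`, `values`,
#'   `label`.
#' @examples
#' ctr <- contour(c(0, 100, 200), c(1, 2, 0.5), label = "so_pair5_S")
#' duration(ctr)
#' @export
contour <- function(times, values, label = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2) {
    stop_cp("a contour needs at least 2 samples", "invalid_contour_error")
  }
  if (length(values) != length(times)) {
    stop_cp("times and values must have equal length", "invalid_contour_error")
  }
  if (any(diff(times) <= 0)) {
    stop_cp("contour times must be strictly increasing", "ordering_error")
  }
  if (!all(is.finite(times)) || !all(is.finite(values))) {
    stop_cp("contour times and values must be finite", "invalid_contour_error")
  }
  structure(list(times = times, values = values, label = label),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour%s: %d samples, %.1f ms, f0 range [%.2f, %.2f] st>\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              length(x$times), duration(x),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Duration of a contour in milliseconds
#' @param x A `contour`.
#' @return Time extent (last minus first sample time), ms.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "contour"))
  x$times[length(x$times)] - x$times[1]
}

#' Convert f0 in Hz to semitones relative to a reference
#'
#' Semitones are 12 * log2(hz / reference). The reference defaults to the
#' median of the input, i.e. per-speaker median normalization.
#'
#' @param hz Numeric vector of f0 values in Hz (> 0).
#' @param reference Reference frequency in Hz; default `median(hz)`.
#' @return Numeric vector of semitone values.
#' @export
hz_to_semitones <- function(hz, reference = stats::median(hz)) {
  if (any(hz <= 0) || reference <= 0) {
    stop_cp("f0 values and reference must be positive", "argument_error")
  }
  12 * log2(hz / reference)
}

#' @rdname hz_to_semitones
#' @param st Numeric vector of semitone values.
#' @export
semitones_to_hz <- function(st, reference) {
  reference * 2^(st / 12)
}

#' Duration-normalize a contour onto a common grid
#'
#' Maps the contour's time extent onto \[0, 1\] and linearly interpolates its
#' values onto `grid_size` equally spaced points. All contours normalized with
#' the same `grid_size` are comparable pointwise regardless of their raw
#' durations, which is what allows a single FPCA over tokens of different
#' lengths.
#'
#' @param contour A [contour()].
#' @param grid_size Number of grid points (>= 10); default 101.
#' @return An object of class `normalized_contour` with fields `grid`
#'   (points on \[0, 1\]), `values`, `label`, and `source_duration_ms`.
#' @export
normalize_time <- function(contour, grid_size = 101) {
  if (!inherits(contour, "contour")) {
    stop_cp("normalize_time expects a contour", "invalid_contour_error")
  }
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 10) {
    stop_cp("grid_size must be an integer >= 10", "argument_error")
  }
  u <- (contour$times - contour$times[1]) / duration(contour)
  grid <- seq(0, 1, length.out = grid_size)
  vals <- stats::approx(u, contour$values, xout = grid, rule = 2)$y
  # endpoints preserved exactly (approx() can round through u)
  vals[1] <- contour$values[1]
  vals[grid_size] <- contour$values[length(contour$values)]
  structure(list(grid = grid, values = vals, label = contour$label,
                 source_duration_ms = duration(contour)),
            class = "normalized_contour")
}

#' @export
print.normalized_contour <- function(x, ...) {
  cat(sprintf("<normalized_contour%s: %d grid points on [0,1]>\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              length(x$grid)))
  invisible(x)
}

#' Read / write a contour as CSV
#'
#' Plain-text fallback format: a CSV with columns `time_ms` and `f0_st`.
#'
#' @param path File path.
#' @param label Optional label attached on read.
#' @return `read_contour_csv()` returns a [contour()]; `write_contour_csv()`
#'   returns `path` invisibly.
#' @export
read_contour_csv <- function(path, label = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "f0_st") %in% names(d))) {
    stop_cp("contour CSV needs columns time_ms, f0_st", "io_error")
  }
  contour(d$time_ms, d$f0_st, label = label)
}

#' @rdname read_contour_csv
#' @param x A [contour()].
#' @export
write_contour_csv <- function(x, path) {
  stopifnot(inherits(x, "contour"))
  utils::write.csv(data.frame(time_ms = x$times, f0_st = x$values),
                   path, row.names = FALSE)
  invisible(path)
}
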
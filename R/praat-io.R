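# Praat text-format I/O. Only the two text dialects are handled: the "full"
# text format (name = value lines) and the "short" format (bare values).
# Praat stores times in seconds; contours in this package are in ms, so times
# are converted on the way in and out. PitchTier values hold whatever scale
# the contour carries (semitones throughout this package).

#' Write a contour as a Praat PitchTier
#'
#' @param x A [contour()].
#' @param path Output file path.
#' @param format `"full"` (default) or `"short"` text dialect.
#' @return `path`, invisibly.
#' @export
write_pitchtier <- function(x, path, format = c("full", "short")) {
  stopifnot(inherits(x, "contour"))
  format <- match.arg(format)
  tmin <- x$times[1] / 1000
  tmax <- x$times[length(x$times)] / 1000
  n <- length(x$times)
  header <- c("File type = \"ooTextFile\"",
              "Object class = \"PitchTier\"", "")
  if (format == "full") {
    body <- c(sprintf("xmin = %.17g", tmin),
              sprintf("xmax = %.17g", tmax),
              sprintf("points: size = %d", n))
    for (i in seq_len(n)) {
      body <- c(body,
                sprintf("points [%d]:", i),
                sprintf("    number = %.17g", x$times[i] / 1000),
                sprintf("    value = %.17g", x$values[i]))
    }
  } else {
    body <- c(sprintf("%.17g", tmin), sprintf("%.17g", tmax),
              sprintf("%d", n),
              as.vector(rbind(sprintf("%.17g", x$times / 1000),
                              sprintf("%.17g", x$values))))
  }
  tryCatch(writeLines(c(header, body), path),
           error = function(e) stop_cp(conditionMessage(e), "io_error"))
  invisible(path)
}

#' Read a Praat PitchTier into a contour
#'
#' Accepts both the full and the short text dialect.
#'
#' @param path PitchTier file path.
#' @param label Optional label for the contour.
#' @return A [contour()] (times in ms).
#' @export
read_pitchtier <- function(path, label = NULL) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_cp(conditionMessage(e), "io_error"))
  if (length(lines) < 3 || !grepl("PitchTier", lines[2])) {
    stop_cp("not a PitchTier text file", "io_error")
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("=", body, fixed = TRUE))) {
    nums <- praat_values(body, c("number", "value"))
    times <- nums$number
    values <- nums$value
  } else {
    v <- as.numeric(body)
    n <- as.integer(v[3])
    pts <- v[-(1:3)]
    times <- pts[seq(1, 2 * n, by = 2)]
    values <- pts[seq(2, 2 * n, by = 2)]
  }
  contour(times * 1000, values, label = label)
}

# Pull "name = value" numbers for the requested names, in file order per name.
praat_values <- function(lines, names) {
  out <- list()
  for (nm in names) {
    rx <- paste0("^\\s*", nm, "\\s*=\\s*(-?[0-9.eE+]+)")
    hit <- regmatches(lines, regexec(rx, lines))
    out[[nm]] <- as.numeric(vapply(hit[lengths(hit) == 2],
                                   `[`, character(1), 2))
  }
  out
}

#' Write interval tiers as a Praat TextGrid
#'
#' @param tiers Named list of tiers; each tier is a data.frame with columns
#'   `xmin`, `xmax` (ms) and `text`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tiers, path) {
  if (!length(tiers) || is.null(names(tiers))) {
    stop_cp("tiers must be a named list of interval data.frames",
            "argument_error")
  }
  xmin <- min(vapply(tiers, function(t) min(t$xmin), 0)) / 1000
  xmax <- max(vapply(tiers, function(t) max(t$xmax), 0)) / 1000
  out <- c("File type = \"ooTextFile\"",
           "Object class = \"TextGrid\"", "",
           sprintf("xmin = %.17g", xmin),
           sprintf("xmax = %.17g", xmax),
           "tiers? <exists>",
           sprintf("size = %d", length(tiers)),
           "item []:")
  for (i in seq_along(tiers)) {
    tier <- tiers[[i]]
    out <- c(out,
             sprintf("    item [%d]:", i),
             "        class = \"IntervalTier\"",
             sprintf("        name = \"%s\"", names(tiers)[i]),
             sprintf("        xmin = %.17g", min(tier$xmin) / 1000),
             sprintf("        xmax = %.17g", max(tier$xmax) / 1000),
             sprintf("        intervals: size = %d", nrow(tier)))
    for (j in seq_len(nrow(tier))) {
      out <- c(out,
               sprintf("        intervals [%d]:", j),
               sprintf("            xmin = %.17g", tier$xmin[j] / 1000),
               sprintf("            xmax = %.17g", tier$xmax[j] / 1000),
               sprintf("            text = \"%s\"", tier$text[j]))
    }
  }
  tryCatch(writeLines(out, path),
           error = function(e) stop_cp(conditionMessage(e), "io_error"))
  invisible(path)
}

#' Read a Praat TextGrid (interval tiers)
#'
#' @param path TextGrid file path.
#' @return Named list of data.frames with columns `xmin`, `xmax` (ms),
#'   `text`.
#' @export
read_textgrid <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_cp(conditionMessage(e), "io_error"))
  if (length(lines) < 3 || !grepl("TextGrid", lines[2])) {
    stop_cp("not a TextGrid text file", "io_error")
  }
  item_at <- grep("^\\s*item \\[[0-9]+\\]:", lines)
  tiers <- list()
  bounds <- c(item_at, length(lines) + 1)
  for (k in seq_along(item_at)) {
    block <- lines[bounds[k]:(bounds[k + 1] - 1)]
    if (!any(grepl("IntervalTier", block))) next
    nm <- sub(".*name = \"(.*)\".*", "\\1",
              grep("name =", block, value = TRUE)[1])
    iv_at <- grep("^\\s*intervals \\[[0-9]+\\]:", block)
    xmin <- xmax <- numeric(0)
    text <- character(0)
    ib <- c(iv_at, length(block) + 1)
    for (j in seq_along(iv_at)) {
      sub_block <- block[ib[j]:(ib[j + 1] - 1)]
      v <- praat_values(sub_block, c("xmin", "xmax"))
      xmin <- c(xmin, v$xmin[1])
      xmax <- c(xmax, v$xmax[1])
      text <- c(text, sub(".*text = \"(.*)\".*", "\\1",
                          grep("text =", sub_block, value = TRUE)[1]))
    }
    tiers[[nm]] <- data.frame(xmin = xmin * 1000, xmax = xmax * 1000,
                              text = text)
  }
  tiers
}
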
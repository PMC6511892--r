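#' RR-interval series
#'
#' Container for a beat-to-beat (RR) interval record, the raw input of all
#' analyses in this package. Intervals are stored in seconds; `beat_times`,
#' when present, holds the cumulative occurrence time of the beat that
#' terminates each interval and must be consistent with the cumulative sum of
#' the intervals to within 1 ms.
#'
#' @param intervals Numeric vector of RR durations in seconds; all strictly
#'   positive.
#' @param beat_times Optional numeric vector of cumulative beat times in
#'   seconds, same length as `intervals`, strictly increasing.
#' @param source_id Free-text label identifying the record.
#' @return An object of class `rr_series`.
#' @examples
#' rr <- rr_series(rep(0.8, 10))
#' rr
#' @export
rr_series <- function(intervals, beat_times = NULL, source_id = "") {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L || anyNA(intervals)) {
    stop("`intervals` must be a non-empty numeric vector without NAs")
  }
  if (any(intervals <= 0)) {
    stop("all RR intervals must be strictly positive (seconds)")
  }
  if (is.null(beat_times)) {
    beat_times <- cumsum(intervals)
  } else {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) != length(intervals)) {
      stop("`beat_times` must have one entry per interval")
    }
    if (any(diff(beat_times) <= 0)) {
      stop("`beat_times` must be strictly increasing")
    }
    # beat k terminates interval k, so successive gaps are the later intervals
    if (length(intervals) > 1L &&
        max(abs(diff(beat_times) - intervals[-1L])) > 1e-3) {
      stop("`beat_times` inconsistent with cumulative intervals (> 1 ms)")
    }
  }
  structure(
    list(intervals = intervals, beat_times = beat_times,
         source_id = as.character(source_id)[1L]),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, %.1f s%s\n",
              length(x$intervals),
              x$beat_times[length(x$beat_times)] - x$beat_times[1L] +
                x$intervals[1L],
              if (nzchar(x$source_id)) paste0(", '", x$source_id, "'") else ""))
  cat(sprintf("  mean RR %.3f s, range [%.3f, %.3f] s\n",
              mean(x$intervals), min(x$intervals), max(x$intervals)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Read an RR-interval file
#'
#' Accepts either plain text with one interval per line (seconds), or CSV with
#' a column `rr_s` (seconds) or `rr_ms` (milliseconds, auto-converted) and an
#' optional cumulative-time column `t_s`. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param source_id Label for the record; defaults to the file name.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, source_id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data in ", path)
  if (grepl(",", lines[1L]) || grepl("[A-Za-z]", lines[1L])) {
    df <- read.csv(text = paste(lines, collapse = "\n"))
    if ("rr_s" %in% names(df)) {
      rr <- df$rr_s
    } else if ("rr_ms" %in% names(df)) {
      rr <- df$rr_ms / 1000
    } else {
      stop("CSV RR input needs an `rr_s` or `rr_ms` column")
    }
    bt <- if ("t_s" %in% names(df)) df$t_s else NULL
    rr_series(rr, beat_times = bt, source_id = source_id)
  } else {
    rr_series(as.numeric(lines), source_id = source_id)
  }
}

#' Write an RR-interval series as CSV
#'
#' Writes columns `rr_s` and `t_s`, readable back with [read_rr()].
#'
#' @param rr An [rr_series()].
#' @param path Output file path.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  write.csv(data.frame(rr_s = rr$intervals, t_s = rr$beat_times),
            path, row.names = FALSE)
  invisible(path)
}

#' Read epoch annotations
#'
#' CSV with columns `label,start_s,end_s` describing protocol epochs.
#'
#' @param path File path.
#' @return A data frame with columns `label`, `start_s`, `end_s`.
#' @export
read_epochs <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop("epoch file needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$end_s <= df$start_s)) stop("epoch end_s must exceed start_s")
  df[need]
}

#' Write epoch annotations
#'
#' @param epochs Data frame with columns `label`, `start_s`, `end_s`.
#' @param path Output file path.
#' @export
write_epochs <- function(epochs, path) {
  write.csv(epochs[c("label", "start_s", "end_s")], path, row.names = FALSE)
  invisible(path)
}
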
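#' Timestamped beat series
#'
#' Container for annotated heartbeat events as emitted by a Holter analyzer:
#' beat times in seconds from record start, one label per beat, and the
#' wall-clock time of record start. Labels follow the usual annotation
#' alphabet: `"N"` (normal/sinus), `"E"` (ectopic), `"A"` (artifact),
#' `"U"` (unknown).
#'
#' @param times Numeric vector of beat times in seconds, strictly increasing.
#' @param labels Character vector of per-beat labels, same length as `times`.
#'   Defaults to all `"N"`.
#' @param record_start_clock Wall-clock time `"HH:MM"` of `times == 0`.
#' @param window Optional two-element character vector recording a wall-clock
#'   analysis window already applied to the series (set by [select_window()]).
#'
#' @return An object of class `beat_series`: a list with elements `times`,
#'   `labels`, `record_start_clock` and (possibly `NULL`) `window`.
#' @seealso [generate_beats()], [read_beats()], [select_window()], [filter_nn()]
#' @export
beat_series <- function(times, labels = NULL,
                        record_start_clock = "00:00", window = NULL) {
  times <- as.numeric(times)
  if (length(times) == 0L) stop("beat series must contain at least one beat")
  if (anyNA(times)) stop("beat times must be finite")
  bad <- which(diff(times) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("beat times must be strictly increasing (violated at row %d)",
                 bad[1L] + 1L))
  }
  if (is.null(labels)) labels <- rep("N", length(times))
  labels <- as.character(labels)
  if (length(labels) != length(times)) {
    stop("labels must have the same length as times")
  }
  ok <- labels %in% c("N", "E", "A", "U")
  if (!all(ok)) stop("labels must be one of 'N', 'E', 'A', 'U'")
  parse_clock(record_start_clock)  # validates format
  structure(list(times = times, labels = labels,
                 record_start_clock = record_start_clock,
                 window = window),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s (record start %s)\n",
              length(x$times), diff(range(x$times)), x$record_start_clock))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$window)) {
    cat("  window:", x$window[1L], "to", x$window[2L], "\n")
  }
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$times)

#' Normal-to-normal (NN) interval series
#'
#' The substrate of every HRV index: intervals between successive accepted
#' sinus beats, in milliseconds, with the onset time (terminating beat, in
#' seconds from record start) of each interval. Rejected beats leave gaps;
#' `gap_before[i]` is `TRUE` when interval `i` does not start at the beat that
#' terminated interval `i - 1`, so downstream modules never treat the two as
#' physiologically successive.
#'
#' @param intervals Numeric vector of NN intervals in ms, all positive.
#' @param onsets Numeric vector of onset times in seconds (time of each
#'   interval's terminating beat), strictly increasing. Defaults to
#'   `cumsum(intervals) / 1000` (a contiguous record starting at 0).
#' @param gap_before Logical vector flagging intervals preceded by a filtering
#'   gap. Defaults to all `FALSE` (contiguous series). The first element is
#'   always treated as `FALSE`.
#' @param n_rejected Count of intervals removed by filtering upstream.
#' @param window Optional wall-clock window applied upstream.
#'
#' @return An object of class `nn_series`.
#' @seealso [filter_nn()], [sdnn()], [rmssd()], [poincare_indices()],
#'   [prsa_indices()]
#' @export
nn_series <- function(intervals, onsets = NULL, gap_before = NULL,
                      n_rejected = 0L, window = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop("empty NN series")
  if (anyNA(intervals) || any(intervals <= 0)) {
    stop("NN intervals must be positive and finite")
  }
  if (is.null(onsets)) onsets <- cumsum(intervals) / 1000
  onsets <- as.numeric(onsets)
  if (length(onsets) != length(intervals)) {
    stop("onsets and intervals must have the same length")
  }
  if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
  if (is.null(gap_before)) gap_before <- rep(FALSE, length(intervals))
  gap_before <- as.logical(gap_before)
  if (length(gap_before) != length(intervals)) {
    stop("gap_before must have the same length as intervals")
  }
  gap_before[1L] <- FALSE
  structure(list(intervals = intervals, onsets = onsets,
                 gap_before = gap_before,
                 n_rejected = as.integer(n_rejected), window = window),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf(
    "<nn_series> %d NN intervals, mean %.1f ms, %d gap(s), %d rejected\n",
    length(x$intervals), mean(x$intervals), sum(x$gap_before), x$n_rejected))
  invisible(x)
}

#' @export
length.nn_series <- function(x) length(x$intervals)

# Indices (into intervals) of the start of each gap-free run.
nn_run_starts <- function(nn) which(c(TRUE, nn$gap_before[-1L]))

# List of integer index vectors, one per gap-free run, in order.
nn_runs <- function(nn) {
  run_id <- cumsum(c(TRUE, nn$gap_before[-1L]))
  unname(split(seq_along(nn$intervals), run_id))
}

# Parse "HH:MM" to seconds after midnight.
parse_clock <- function(clock) {
  if (!is.character(clock) || length(clock) != 1L ||
      !grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", clock)) {
    stop(sprintf("invalid clock time '%s' (expected HH:MM)",
                 paste(clock, collapse = ",")))
  }
  parts <- as.integer(strsplit(clock, ":", fixed = TRUE)[[1L]])
  parts[1L] * 3600 + parts[2L] * 60
}
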
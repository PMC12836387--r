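#' Read beat annotations or a plain RR list
#'
#' Auto-detects the format: a file whose first line is the header
#' `time_s,label` is parsed as a beat-annotation CSV; otherwise the file must
#' be a plain list of RR intervals, one ms value per line, which is converted
#' to cumulative beat times with all labels `"N"`.
#'
#' @param path Path to the input file.
#' @param record_start_clock Wall clock `"HH:MM"` assigned to time 0 (used for
#'   RR lists and for CSVs, which do not carry a clock).
#' @return A [beat_series()].
#' @export
read_beats <- function(path, record_start_clock = "00:00") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("empty input file: %s", path))
  if (grepl("^\\s*time_s\\s*,\\s*label\\s*$", first)) {
    df <- utils::read.csv(path, colClasses = c("numeric", "character"))
    if (nrow(df) == 0L) stop(sprintf("no beats in file: %s", path))
    bad <- which(diff(df$time_s) <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("non-monotone beat times in %s at data row %d",
                   path, bad[1L] + 1L))
    }
    beat_series(df$time_s, trimws(df$label),
                record_start_clock = record_start_clock)
  } else {
    rr <- scan(path, what = numeric(), quiet = TRUE)
    if (length(rr) == 0L) stop(sprintf("no RR intervals in file: %s", path))
    if (any(rr <= 0)) stop(sprintf("nonpositive RR interval in %s", path))
    beat_series(cumsum(rr) / 1000, record_start_clock = record_start_clock)
  }
}

#' Select a wall-clock analysis window
#'
#' Retains beats whose wall-clock time (record start clock plus elapsed time)
#' lies in the half-open window `[start, end)`. Day indices count midnights
#' after record start: day 0 is the starting (calendar) day, day 1 begins at
#' the first midnight after recording started. The default window — midnight
#' of the first night to 08:00 of the second day — is the nocturnal span used
#' for sleep HRV on 48-h Holter records.
#'
#' @param beats A [beat_series()].
#' @param start_clock,end_clock Window boundaries, `"HH:MM"`.
#' @param start_day,end_day Day indices (midnights after record start) of the
#'   two boundaries.
#' @return A [beat_series()] restricted to the window, with the window
#'   recorded in its `window` field.
#' @examples
#' b <- beat_series(seq(1, 86400, by = 1), record_start_clock = "20:00")
#' w <- select_window(b, "00:00", "08:00", start_day = 1, end_day = 1)
#' range(w$times)  # 4 h to 12 h elapsed
#' @export
select_window <- function(beats, start_clock = "00:00", end_clock = "08:00",
                          start_day = 1L, end_day = 2L) {
  stopifnot(inherits(beats, "beat_series"), start_day >= 0, end_day >= 0)
  t0 <- parse_clock(beats$record_start_clock)
  elapsed_start <- start_day * 86400 + parse_clock(start_clock) - t0
  elapsed_end <- end_day * 86400 + parse_clock(end_clock) - t0
  if (elapsed_end <= elapsed_start) {
    stop("empty selection: window end does not fall after window start; check clocks and day indices")
  }
  keep <- beats$times >= elapsed_start & beats$times < elapsed_end
  if (!any(keep)) {
    stop("empty selection: no beats fall in the requested window; check clocks and day indices")
  }
  beat_series(beats$times[keep], beats$labels[keep],
              record_start_clock = beats$record_start_clock,
              window = c(sprintf("day %d %s", start_day, start_clock),
                         sprintf("day %d %s", end_day, end_clock)))
}

#' NN-interval filtering rules
#'
#' Physiologic and step-change bounds used by [filter_nn()]. The defaults
#' (200–2000 ms, 25\% maximum relative step, non-normal beats dropped) are
#' generous bounds for dogs, whose marked respiratory sinus arrhythmia
#' produces large legitimate beat-to-beat swings.
#'
#' @param min_ms,max_ms Acceptable NN interval range, ms.
#' @param max_rel_step Maximum allowed `|change| / previous` between an
#'   interval and the previously retained interval, in (0, 1\].
#' @param drop_nonnormal Reject intervals with a non-sinus endpoint beat.
#' @return An object of class `filter_rules`.
#' @export
filter_rules <- function(min_ms = 200, max_ms = 2000, max_rel_step = 0.25,
                         drop_nonnormal = TRUE) {
  stopifnot(min_ms > 0, min_ms < max_ms,
            max_rel_step > 0, max_rel_step <= 1)
  structure(list(min_ms = min_ms, max_ms = max_ms,
                 max_rel_step = max_rel_step,
                 drop_nonnormal = isTRUE(drop_nonnormal)),
            class = "filter_rules")
}

#' Reduce beats to a clean NN-interval series
#'
#' Forms intervals between successive beats and rejects an interval when
#' either endpoint beat is non-normal (if `drop_nonnormal`), when it falls
#' outside `[min_ms, max_ms]`, or when its relative step from the previously
#' retained interval exceeds `max_rel_step`. Rejected intervals are counted
#' and leave gaps (onset times are kept; nothing is interpolated here), so
#' downstream modules can refuse to treat non-adjacent beats as successive.
#'
#' Re-applying the same rules to an already-filtered series changes nothing:
#' the method for `nn_series` re-runs the interval-level rules so filtering is
#' idempotent.
#'
#' @param x A [beat_series()] (at least 3 beats) or an [nn_series()].
#' @param rules A [filter_rules()].
#' @return An [nn_series()].
#' @export
filter_nn <- function(x, rules = filter_rules()) UseMethod("filter_nn")

#' @export
filter_nn.beat_series <- function(x, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  if (length(x$times) < 3L) stop("need at least 3 beats to form NN intervals")
  intervals <- diff(x$times) * 1000
  onsets <- x$times[-1L]
  start_ok <- TRUE
  if (rules$drop_nonnormal) {
    normal <- x$labels == "N"
    start_ok <- normal[-length(normal)] & normal[-1L]
  }
  apply_interval_rules(intervals, onsets, start_ok, rules,
                       window = x$window)
}

#' @export
filter_nn.nn_series <- function(x, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  apply_interval_rules(x$intervals, x$onsets, TRUE, rules,
                       window = x$window, prior_rejected = x$n_rejected)
}

apply_interval_rules <- function(intervals, onsets, label_ok, rules,
                                 window = NULL, prior_rejected = 0L) {
  n <- length(intervals)
  keep <- rep(label_ok, length.out = n) &
    intervals >= rules$min_ms & intervals <= rules$max_ms
  # sequential step rule against the previously *retained* interval
  last <- NA_real_
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (!is.na(last) && abs(intervals[i] - last) / last > rules$max_rel_step) {
      keep[i] <- FALSE
      next
    }
    last <- intervals[i]
  }
  if (sum(keep) < 2L) stop("insufficient NN data after filtering")
  kept_int <- intervals[keep]
  kept_on <- onsets[keep]
  start_times <- kept_on - kept_int / 1000
  gap_before <- c(FALSE, abs(start_times[-1L] - kept_on[-length(kept_on)]) > 1e-6)
  nn_series(kept_int, kept_on, gap_before,
            n_rejected = prior_rejected + sum(!keep), window = window)
}

#' Write an NN series to CSV
#'
#' Writes the `onset_s,nn_ms` dialect (one row per retained interval).
#'
#' @param nn An [nn_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nn <- function(nn, path) {
  stopifnot(inherits(nn, "nn_series"))
  utils::write.csv(data.frame(onset_s = nn$onsets, nn_ms = nn$intervals),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
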
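#' Time-domain linear HRV indices
#'
#' `sdnn()` is the sample standard deviation (denominator N − 1) of all NN
#' intervals in the window; `rmssd()` the root mean square of successive
#' differences (denominator = number of differences), which indexes vagal
#' activity via respiratory sinus arrhythmia; `mean_hr()` the mean heart rate
#' `60000 / mean(NN)`. Successive differences are never taken across a
#' filtering gap — the neighbors of a rejected beat are not physiologically
#' successive.
#'
#' @param nn An [nn_series()].
#' @return Scalar index value (ms for `sdnn`/`rmssd`, bpm for `mean_hr`).
#' @examples
#' nn <- nn_series(rep(c(500, 510), 10))
#' sdnn(nn)
#' rmssd(nn)   # 10: every successive difference is +-10 ms
#' mean_hr(nn)
#' @export
sdnn <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  if (length(nn$intervals) < 2L) stop("sdnn needs at least 2 NN intervals")
  stats::sd(nn$intervals)
}

#' @rdname sdnn
#' @export
rmssd <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  if (length(nn$intervals) < 2L) stop("rmssd needs at least 2 NN intervals")
  d <- successive_differences(nn)
  if (length(d) == 0L) stop("rmssd: no successive pairs (every pair spans a gap)")
  sqrt(mean(d^2))
}

#' @rdname sdnn
#' @export
mean_hr <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  60000 / mean(nn$intervals)
}

# Successive NN differences within gap-free runs only.
successive_differences <- function(nn) {
  d <- diff(nn$intervals)
  d[!nn$gap_before[-1L]]
}

#' All time-domain indices at once
#'
#' @param nn An [nn_series()].
#' @return A list with `sdnn` (ms), `rmssd` (ms), `mean_hr` (bpm) and
#'   `n_intervals`.
#' @export
time_domain_indices <- function(nn) {
  list(sdnn = sdnn(nn), rmssd = rmssd(nn), mean_hr = mean_hr(nn),
       n_intervals = length(nn$intervals))
}
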
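# Spectral analysis of the RR tachogram: uniform resampling, PSD estimation
# and band-power integration with the HF/LF normalizations.

# Default band edges (Hz): TP 0-0.4 partitioned into ULF 0-0.00333,
# VLF 0.00333-0.04, LF 0.04-0.15, HF 0.15-0.4.
DEFAULT_BAND_EDGES <- c(0, 0.00333, 0.04, 0.15, 0.4)

#' Resample an NN series to an evenly sampled tachogram
#'
#' Cubic-spline interpolation of the (onset, interval) points onto a uniform
#' grid (default 4 Hz). Inter-onset gaps longer than `max_gap_s` (rejected
#' beats, dropouts) are bridged linearly between their bracketing points
#' rather than splined, and counted in the result, so spline overshoot cannot
#' inject spurious power. A linear trend (including the mean) is removed by
#' default.
#'
#' @param nn An [nn_series()] with at least 3 intervals spanning at least
#'   5 minutes.
#' @param fs Sampling rate, Hz; must exceed 0.8 Hz (twice the 0.4 Hz upper
#'   analysis edge).
#' @param detrend Remove a least-squares linear trend.
#' @param max_gap_s Gap length (s) beyond which interpolation is linear.
#' @return An object of class `even_tachogram`: list with `fs`, `t0` (time of
#'   the first sample, s), `values` (ms), `detrended`, `n_bridged_gaps`.
#' @export
resample_tachogram <- function(nn, fs = 4, detrend = TRUE, max_gap_s = 5) {
  stopifnot(inherits(nn, "nn_series"))
  if (length(nn$intervals) < 3L) stop("need at least 3 NN intervals")
  if (fs <= 0.8) stop("fs must exceed 0.8 Hz (twice the 0.4 Hz band edge)")
  span <- nn$onsets[length(nn$onsets)] - nn$onsets[1L]
  if (span < 300) stop("NN series spans less than 5 minutes")
  grid <- seq(nn$onsets[1L], nn$onsets[length(nn$onsets)], by = 1 / fs)
  vals <- stats::spline(nn$onsets, nn$intervals, xout = grid,
                        method = "fmm", ties = "ordered")$y
  # linear bridges across long gaps
  gap_idx <- which(diff(nn$onsets) > max_gap_s)
  for (g in gap_idx) {
    inside <- grid > nn$onsets[g] & grid < nn$onsets[g + 1L]
    if (any(inside)) {
      vals[inside] <- stats::approx(nn$onsets[g:(g + 1L)],
                                    nn$intervals[g:(g + 1L)],
                                    xout = grid[inside])$y
    }
  }
  if (detrend) vals <- stats::lm.fit(cbind(1, grid), vals)$residuals
  structure(list(fs = fs, t0 = grid[1L], values = as.numeric(vals),
                 detrended = isTRUE(detrend),
                 n_bridged_gaps = length(gap_idx)),
            class = "even_tachogram")
}

#' Estimate the tachogram power spectral density
#'
#' One-sided PSD in ms²/Hz. The default `"periodogram"` uses the full record
#' with a rectangular window, so the discrete Parseval relation holds exactly:
#' `sum(density) * df` equals the mean square of the signal. `"welch"`
#' averages Hann-windowed 600-s segments with 50\% overlap for variance
#' reduction at the cost of ULF resolution.
#'
#' @param tachogram An [resample_tachogram()] result.
#' @param method `"periodogram"` or `"welch"`.
#' @param segment_s Welch segment length, seconds.
#' @return An object of class `hrv_psd`: list with `freqs` (Hz, from 0 to
#'   fs/2), `density` (ms²/Hz), `df`, `method`.
#' @export
estimate_psd <- function(tachogram, method = c("periodogram", "welch"),
                         segment_s = 600) {
  stopifnot(inherits(tachogram, "even_tachogram"))
  method <- match.arg(method)
  fs <- tachogram$fs
  x <- tachogram$values
  if (method == "periodogram") {
    out <- one_sided_periodogram(x, fs, window = NULL)
  } else {
    nper <- round(segment_s * fs)
    if (nper > length(x)) nper <- length(x)
    step <- max(1L, floor(nper / 2))
    starts <- seq(1L, length(x) - nper + 1L, by = step)
    w <- hann_window(nper)
    specs <- lapply(starts, function(s) {
      one_sided_periodogram(x[s:(s + nper - 1L)], fs, window = w)
    })
    dens <- rowMeans(do.call(cbind, lapply(specs, `[[`, "density")))
    out <- list(freqs = specs[[1L]]$freqs, density = dens)
  }
  structure(list(freqs = out$freqs, density = pmax(out$density, 0),
                 df = out$freqs[2L] - out$freqs[1L], method = method),
            class = "hrv_psd")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# One-sided periodogram normalized so sum(density)*df = mean(x^2) with a
# rectangular window; with a taper, normalization is by the window power.
one_sided_periodogram <- function(x, fs, window = NULL) {
  n <- length(x)
  u <- 1
  if (!is.null(window)) {
    u <- mean(window^2)
    x <- x * window
  }
  xf <- stats::fft(x)
  n_half <- floor(n / 2) + 1L
  p <- (Mod(xf[seq_len(n_half)])^2) / (n * fs * u)
  scale <- rep(2, n_half)
  scale[1L] <- 1
  if (n %% 2 == 0) scale[n_half] <- 1  # Nyquist bin not duplicated
  list(freqs = (seq_len(n_half) - 1L) * fs / n, density = p * scale)
}

#' Integrate PSD band powers and normalized indices
#'
#' Each band power is the rectangle-rule sum of `density * df` over frequency
#' bins whose center lies in the half-open band `[lo, hi)`; total power is the
#' sum of the four bands, so band additivity holds by construction. The
#' normalized indices are `nHF = HF / (LF + HF)`, `nLF = LF / (LF + HF)` and
#' the ratio `LF/HF`; they are dimensionless and returned as `NA` (flagged
#' missing) when their denominator is zero.
#'
#' @param psd An [estimate_psd()] result.
#' @param edges Ascending band edges, Hz (ULF/VLF/LF/HF partition of total
#'   power); the last edge must not exceed the Nyquist frequency.
#' @return An object of class `spectral_indices`: list with `tp`, `ulf`,
#'   `vlf`, `lf`, `hf` (ms²), `n_hf`, `n_lf`, `lf_hf` (dimensionless),
#'   `band_edges`.
#' @export
band_powers <- function(psd, edges = DEFAULT_BAND_EDGES) {
  stopifnot(inherits(psd, "hrv_psd"))
  if (length(edges) != 5L || is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be 5 strictly ascending values")
  }
  if (edges[5L] > max(psd$freqs) + 1e-12) {
    stop("last band edge exceeds the Nyquist frequency")
  }
  band <- function(lo, hi) {
    sel <- psd$freqs >= lo & psd$freqs < hi
    sum(psd$density[sel]) * psd$df
  }
  ulf <- band(edges[1L], edges[2L])
  vlf <- band(edges[2L], edges[3L])
  lf <- band(edges[3L], edges[4L])
  hf <- band(edges[4L], edges[5L])
  denom <- lf + hf
  structure(list(tp = ulf + vlf + lf + hf, ulf = ulf, vlf = vlf,
                 lf = lf, hf = hf,
                 n_hf = if (denom > 0) hf / denom else NA_real_,
                 n_lf = if (denom > 0) lf / denom else NA_real_,
                 lf_hf = if (hf > 0) lf / hf else NA_real_,
                 band_edges = edges),
            class = "spectral_indices")
}

#' Frequency-domain indices from an NN series
#'
#' Convenience wrapper: resample, estimate the PSD and integrate the bands.
#' In `"welch"` mode the ULF band (fundamental about 3.5e-5 Hz over 8 h) is
#' unresolvable from 600-s segments, so it is taken from a full-record
#' periodogram while VLF/LF/HF come from the Welch estimate; the result is
#' marked `hybrid`.
#'
#' @param nn An [nn_series()].
#' @param fs Resampling rate, Hz.
#' @param method PSD estimator passed to [estimate_psd()].
#' @param edges Band edges passed to [band_powers()].
#' @return A `spectral_indices` object (with `method` and `hybrid` fields).
#' @export
spectral_indices <- function(nn, fs = 4, method = c("periodogram", "welch"),
                             edges = DEFAULT_BAND_EDGES) {
  method <- match.arg(method)
  tach <- resample_tachogram(nn, fs = fs)
  if (method == "periodogram") {
    res <- band_powers(estimate_psd(tach, "periodogram"), edges)
    res$hybrid <- FALSE
  } else {
    full <- band_powers(estimate_psd(tach, "periodogram"), edges)
    res <- band_powers(estimate_psd(tach, "welch"), edges)
    res$ulf <- full$ulf
    res$tp <- res$ulf + res$vlf + res$lf + res$hf
    res$hybrid <- TRUE
  }
  res$method <- method
  res
}

#' Write a PSD to CSV
#'
#' Writes the `freq_hz,density_ms2_per_hz` export dialect.
#'
#' @param psd An [estimate_psd()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psd <- function(psd, path) {
  stopifnot(inherits(psd, "hrv_psd"))
  utils::write.csv(data.frame(freq_hz = psd$freqs,
                              density_ms2_per_hz = psd$density),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
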
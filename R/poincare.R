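#' Poincaré plot pairs
#'
#' The Poincaré plot graphs every NN interval against its successor:
#' pairs \eqn{(x_i, y_i) = (NN_i, NN_{i+1})} over successive retained
#' intervals. Pairs spanning a filtering gap are skipped — the two intervals
#' are not physiologically adjacent.
#'
#' @param nn An [nn_series()] with at least 3 intervals.
#' @return A data frame with columns `x` and `y` (ms), one row per pair.
#' @export
poincare_pairs <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  if (length(nn$intervals) < 3L) stop("need at least 3 NN intervals")
  i <- which(!nn$gap_before[-1L])  # pair (i, i+1) valid when no gap before i+1
  if (length(i) < 2L) stop("fewer than 2 Poincaré pairs after gap exclusion")
  data.frame(x = nn$intervals[i], y = nn$intervals[i + 1L])
}

#' Poincaré ellipse descriptors SD1, SD2 and their ratios
#'
#' Fits the standard ellipse geometry to the Poincaré cloud. SD1 — the width
#' of the ellipse — is the dispersion of the points transverse to the identity
#' line: the population standard deviation of the signed distances
#' \eqn{d_{1,i} = (y_i - x_i)/\sqrt{2}}. SD2 — the length of the ellipse — is
#' the dispersion along the identity-line direction about the centroid:
#' the population standard deviation of
#' \eqn{d_{2,i} = (x_i + y_i - 2m)/\sqrt{2}} with \eqn{m} the mean over all
#' pair coordinates. Both use denominator `n_pairs`, which makes the
#' projection form agree exactly with the closed forms
#' \eqn{SD1^2 = \frac{1}{2}Var(y - x)} and \eqn{SD2^2 = \frac{1}{2}Var(x + y)}.
#'
#' SD1 captures fast (vagal) beat-to-beat variability; SD2 total slow-plus-fast
#' variability. Their ratios SD1/SD2 and SD2/SD1 index autonomic balance:
#' sympathetic predominance lowers SD1/SD2 and raises SD2/SD1. A ratio whose
#' denominator is zero is returned as `NA` (flagged missing).
#'
#' @param nn An [nn_series()].
#' @return An object of class `poincare_indices`: list with `sd1`, `sd2` (ms),
#'   `sd1_sd2`, `sd2_sd1` (dimensionless), `n_pairs`, `mean_rr` (ms).
#' @examples
#' nn <- nn_series(rep(c(500, 510), 50))
#' poincare_indices(nn)  # sd1 = 10/sqrt(2), sd2 ~ 0
#' @export
poincare_indices <- function(nn) {
  pairs <- poincare_pairs(nn)
  x <- pairs$x
  y <- pairs$y
  m <- mean(c(x, y))
  d1 <- (y - x) / sqrt(2)
  d2 <- (x + y - 2 * m) / sqrt(2)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sd1 <- pop_sd(d1)
  sd2 <- pop_sd(d2)
  structure(list(sd1 = sd1, sd2 = sd2,
                 sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_,
                 sd2_sd1 = if (sd1 > 0) sd2 / sd1 else NA_real_,
                 n_pairs = nrow(pairs), mean_rr = m),
            class = "poincare_indices")
}

#' @export
print.poincare_indices <- function(x, ...) {
  cat(sprintf(
    "<poincare_indices> SD1 %.2f ms, SD2 %.2f ms, SD1/SD2 %.3f, SD2/SD1 %.3f (%d pairs)\n",
    x$sd1, x$sd2, x$sd1_sd2, x$sd2_sd1, x$n_pairs))
  invisible(x)
}

#' Export Poincaré pairs for external plotting
#'
#' Writes the `rr_n_ms,rr_n1_ms` scatter dialect.
#'
#' @param nn An [nn_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_poincare <- function(nn, path) {
  pairs <- poincare_pairs(nn)
  utils::write.csv(data.frame(rr_n_ms = pairs$x, rr_n1_ms = pairs$y),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
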
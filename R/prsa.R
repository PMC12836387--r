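# Phase-rectified signal averaging (PRSA): align windows of the NN sequence
# at deceleration (RR lengthening) or acceleration (RR shortening) anchors,
# average them phase-locked, and contrast the averaged curve around the anchor
# to obtain deceleration capacity (DC) or acceleration capacity (AC).

#' PRSA configuration
#'
#' @param L Half-window length in beats (default 5, at least 2); the averaged
#'   curve spans `k = -L, ..., L - 1` around the anchor at `k = 0`.
#' @param anchor_mode `"deceleration"` (RR lengthenings, yields DC) or
#'   `"acceleration"` (RR shortenings, yields AC).
#' @param rel_threshold Anchor step-size limit (> 1, default 1.05): a
#'   deceleration anchor must satisfy `NN[i-1] < NN[i] <= rel_threshold *
#'   NN[i-1]`, excluding jumps larger than 5\% that are more likely artifacts
#'   than autonomic events; symmetrically for accelerations.
#' @return An object of class `prsa_config`.
#' @export
prsa_config <- function(L = 5L, anchor_mode = c("deceleration", "acceleration"),
                        rel_threshold = 1.05) {
  L <- as.integer(L)
  if (L < 2L) stop("PRSA half-window L must be at least 2")
  if (rel_threshold <= 1) stop("rel_threshold must exceed 1")
  structure(list(L = L, anchor_mode = match.arg(anchor_mode),
                 rel_threshold = rel_threshold),
            class = "prsa_config")
}

#' Find PRSA anchor points
#'
#' Deceleration anchors are interval indices `i` with
#' `NN[i] > NN[i-1]` and `NN[i] <= rel_threshold * NN[i-1]`; acceleration
#' anchors have `NN[i] < NN[i-1]` and `NN[i] >= NN[i-1] / rel_threshold`.
#' Ties are anchors in neither mode. An anchor must have `L` intervals before
#' it and `L - 1` after it within the same gap-free run, so the averaging
#' window never spans a filtering gap.
#'
#' @param nn An [nn_series()].
#' @param cfg A [prsa_config()].
#' @return Integer vector of anchor indices into `nn$intervals` (possibly
#'   empty).
#' @export
find_anchors <- function(nn, cfg = prsa_config()) {
  stopifnot(inherits(nn, "nn_series"), inherits(cfg, "prsa_config"))
  v <- nn$intervals
  anchors <- integer(0)
  for (run in nn_runs(nn)) {
    nrun <- length(run)
    if (nrun < 2L * cfg$L) next
    # candidate positions within the run (1-based): L+1 .. nrun - L + 1
    pos <- (cfg$L + 1L):(nrun - cfg$L + 1L)
    cur <- v[run[pos]]
    prev <- v[run[pos - 1L]]
    hit <- if (cfg$anchor_mode == "deceleration") {
      cur > prev & cur <= cfg$rel_threshold * prev
    } else {
      cur < prev & cur >= prev / cfg$rel_threshold
    }
    anchors <- c(anchors, run[pos[hit]])
  }
  anchors
}

#' Phase-rectified average curve
#'
#' Averages the NN sequence phase-locked to the anchors:
#' \eqn{X(k) = } mean over anchors \eqn{i} of \eqn{NN_{i+k}}, for
#' \eqn{k = -L, ..., L - 1}.
#'
#' @param nn An [nn_series()].
#' @param anchors Anchor indices from [find_anchors()].
#' @param cfg A [prsa_config()].
#' @return An object of class `prsa_indices`: list with `k`, `x` (the curve,
#'   ms), `capacity` (ms; DC in deceleration mode, AC in acceleration mode),
#'   `n_anchors`, `anchor_mode`, `L`.
#' @export
prsa_curve <- function(nn, anchors, cfg = prsa_config()) {
  stopifnot(inherits(nn, "nn_series"), inherits(cfg, "prsa_config"))
  if (length(anchors) == 0L) stop("no anchors")
  k <- (-cfg$L):(cfg$L - 1L)
  x <- vapply(k, function(kk) mean(nn$intervals[anchors + kk]), numeric(1))
  res <- structure(list(k = k, x = x, capacity = NA_real_,
                        n_anchors = length(anchors),
                        anchor_mode = cfg$anchor_mode, L = cfg$L),
                   class = "prsa_indices")
  res$capacity <- prsa_capacity(res)
  res
}

#' Acceleration/deceleration capacity from a PRSA curve
#'
#' The capacity is the Haar-like contrast of the averaged curve at the anchor:
#' \deqn{[X(0) + X(1) - X(-1) - X(-2)] / 4} (ms). In deceleration mode this is
#' the deceleration capacity DC (positive when the rhythm keeps lengthening
#' around decelerations); in acceleration mode the acceleration capacity AC
#' (typically negative).
#'
#' @param indices A `prsa_indices` object from [prsa_curve()].
#' @return Capacity in ms.
#' @export
prsa_capacity <- function(indices) {
  stopifnot(inherits(indices, "prsa_indices"))
  xk <- function(kk) indices$x[match(kk, indices$k)]
  (xk(0L) + xk(1L) - xk(-1L) - xk(-2L)) / 4
}

#' PRSA indices from an NN series
#'
#' Convenience wrapper: [find_anchors()] then [prsa_curve()].
#'
#' @param nn An [nn_series()].
#' @param cfg A [prsa_config()].
#' @return A `prsa_indices` object.
#' @export
prsa_indices <- function(nn, cfg = prsa_config()) {
  prsa_curve(nn, find_anchors(nn, cfg), cfg)
}

#' @export
print.prsa_indices <- function(x, ...) {
  cat(sprintf("<prsa_indices> %s capacity %.3f ms from %d anchors (L = %d)\n",
              x$anchor_mode, x$capacity, x$n_anchors, x$L))
  invisible(x)
}

#' Export a PRSA curve to CSV
#'
#' Writes the `k,x_k_ms` dialect.
#'
#' @param indices A `prsa_indices` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prsa <- function(indices, path) {
  stopifnot(inherits(indices, "prsa_indices"))
  utils::write.csv(data.frame(k = indices$k, x_k_ms = indices$x),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
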
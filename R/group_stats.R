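# Paired Pre/Post comparison: exact Wilcoxon signed-rank test, quartile
# summaries and the formatted results table.

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Computes differences `post - pre`, drops zero differences (the classical
#' exact procedure), ranks the absolute differences with midranks for ties,
#' and takes `W` = sum of ranks of positive differences. For `m <= 20`
#' non-zero differences the two-sided p-value is exact over all `2^m`
#' equiprobable sign assignments of the observed |difference| multiset:
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))`, both tails including the
#' observed statistic. For `m > 20` a normal approximation with tie correction
#' and continuity correction is used and flagged in the result.
#'
#' The null distribution is evaluated by dynamic programming over the
#' (doubled, hence integer) rank sums, which enumerates the same `2^m`
#' assignments as the naive scan without materializing them.
#'
#' @param pre,post Paired numeric vectors of equal length (at least 2 pairs).
#' @return A list with `p_value`, `statistic` (W), `n_nonzero`, `method`
#'   (`"exact"` or `"normal"`), and `all_zero` (TRUE when every difference was
#'   zero, in which case `p_value = 1` with a warning).
#' @examples
#' exact_wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6),
#'                            c(2, 3, 4, 5, 6, 7))$p_value  # 2/2^6 = 0.03125
#' @export
exact_wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  if (length(pre) < 2L) stop("need at least 2 pairs")
  if (anyNA(pre) || anyNA(post)) stop("missing values in paired data")
  d <- post - pre
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    warning("all paired differences are zero; p-value set to 1")
    return(list(p_value = 1, statistic = NA_real_, n_nonzero = 0L,
                method = "exact", all_zero = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= 20L) {
    r2 <- as.integer(round(2 * r))  # doubled midranks are integers
    total <- sum(r2)
    # counts[s + 1] = number of sign assignments with doubled rank sum s
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(total + 1L - rr)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / 2^m
    p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^m
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(abs(d))
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(p_value = p, statistic = w, n_nonzero = m, method = method,
       all_zero = FALSE)
}

#' Median and quartile summary
#'
#' Linear-interpolation percentiles (the convention where the p-th percentile
#' of the sorted vector `v` is `v[(n - 1) * p]` with fractional indexing,
#' i.e. `stats::quantile()` type 7). The IQR is the difference between the
#' 75th and 25th percentiles.
#'
#' @param values Numeric vector (length at least 1; `NA`s removed).
#' @return A list with `median`, `q25`, `q75`, `iqr`, `min`, `max`, `n`.
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values to summarize")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2L], q25 = q[1L], q75 = q[3L], iqr = q[3L] - q[1L],
       min = min(values), max = max(values), n = length(values))
}

#' Paired Pre/Post comparison for one index
#'
#' Bundles the per-subject values of one HRV index under both conditions with
#' their quartile summaries and the exact signed-rank p-value.
#'
#' @param index_name Name of the index.
#' @param pre,post Per-subject values, paired by position.
#' @param units Unit string for the results table (e.g. `"ms"`).
#' @return An object of class `paired_comparison`.
#' @export
paired_comparison <- function(index_name, pre, post, units = "") {
  ok <- !is.na(pre) & !is.na(post)
  if (sum(ok) < 2L) stop(sprintf("index %s: fewer than 2 complete pairs",
                                 index_name))
  test <- exact_wilcoxon_signed_rank(pre[ok], post[ok])
  structure(list(index_name = index_name, units = units,
                 pre = pre[ok], post = post[ok],
                 summary_pre = summarize_values(pre[ok]),
                 summary_post = summarize_values(post[ok]),
                 p_value = test$p_value, test = test),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: Pre %.3g (%.3g-%.3g) vs Post %.3g (%.3g-%.3g), p = %.4g\n",
              x$index_name, x$summary_pre$median, x$summary_pre$q25,
              x$summary_pre$q75, x$summary_post$median, x$summary_post$q25,
              x$summary_post$q75, x$p_value))
  invisible(x)
}

#' Assemble the Pre/Post results table
#'
#' One row per index with `"median (q25-q75)"` cells (or `"median (min-max)"`
#' with `range_style = "minmax"`), the exact p-value, and a `"*"` marker for
#' p strictly below 0.05.
#'
#' @param comparisons List of [paired_comparison()] objects.
#' @param digits Decimal places used in the formatted cells.
#' @param range_style `"iqr"` for (q25-q75) or `"minmax"` for (min-max).
#' @return A data frame with columns `Indices`, `Units`, `Pre`, `Post`,
#'   `p_value`.
#' @export
results_table <- function(comparisons, digits = 2,
                          range_style = c("iqr", "minmax")) {
  if (length(comparisons) == 0L) stop("no comparisons to tabulate")
  range_style <- match.arg(range_style)
  fmt_cell <- function(s) {
    lo <- if (range_style == "iqr") s$q25 else s$min
    hi <- if (range_style == "iqr") s$q75 else s$max
    sprintf("%.*f (%.*f–%.*f)", digits, s$median, digits, lo, digits, hi)
  }
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(inherits(cmp, "paired_comparison"))
    data.frame(Indices = cmp$index_name, Units = cmp$units,
               Pre = fmt_cell(cmp$summary_pre),
               Post = fmt_cell(cmp$summary_post),
               p_value = paste0(format(round(cmp$p_value, 4), scientific = FALSE),
                                if (cmp$p_value < 0.05) "*" else ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
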
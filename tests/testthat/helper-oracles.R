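# Independent naive implementations used as oracles. Deliberately written as
# plain loops / full enumerations, sharing no code with the package.

brute_rmssd <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}

# Closed-form Poincaré descriptors from the variance identities
# sd1^2 = Var(y - x) / 2, sd2^2 = Var(x + y) / 2 (population variances).
brute_sd1_sd2 <- function(x, y) {
  pvar <- function(v) mean((v - mean(v))^2)
  c(sd1 = sqrt(pvar(y - x) / 2), sd2 = sqrt(pvar(x + y) / 2))
}

# Naive PRSA on a gap-free interval vector (1-based indices).
brute_prsa <- function(v, L, mode, thr) {
  n <- length(v)
  anchors <- integer(0)
  for (i in seq_len(n)) {
    if (i - L < 1 || i + L - 1 > n || i < 2) next
    ok <- if (mode == "deceleration") {
      v[i] > v[i - 1] && v[i] <= thr * v[i - 1]
    } else {
      v[i] < v[i - 1] && v[i] >= v[i - 1] / thr
    }
    if (ok) anchors <- c(anchors, i)
  }
  if (length(anchors) == 0) return(list(anchors = anchors))
  ks <- (-L):(L - 1)
  curve <- numeric(length(ks))
  for (j in seq_along(ks)) {
    tot <- 0
    for (a in anchors) tot <- tot + v[a + ks[j]]
    curve[j] <- tot / length(anchors)
  }
  xk <- function(k) curve[which(ks == k)]
  list(anchors = anchors, curve = curve,
       capacity = (xk(0) + xk(1) - xk(-1) - xk(-2)) / 4)
}

# Exact two-sided signed-rank p by materializing all 2^m sign assignments.
brute_wilcoxon_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w), mean(w_all >= w)))
}

# Random gap-free NN series: slow AR(1) wander plus beat-to-beat noise,
# bounded well inside physiologic limits.
random_nn <- function(n, seed) {
  set.seed(seed)
  wander <- as.numeric(stats::arima.sim(list(ar = 0.95), n, sd = 3))
  nn_series(pmin(pmax(550 + wander + stats::rnorm(n, 0, 8), 300), 1500))
}
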
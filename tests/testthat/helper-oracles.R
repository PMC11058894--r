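# Independent brute-force oracles, deliberately written from first principles
# (normal equations, two-pass moments, O(n^2) scans) and kept free of any
# package internals.

oracle_ols <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  list(beta0 = beta[1], beta1 = beta[2], r_squared = sxy^2 / (sxx * syy))
}

oracle_bland_altman <- function(d1, d2) {
  d <- d1 - d2
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  pct <- 100 * d / ((d1 + d2) / 2)
  list(mean_diff = m, loa_low = m - 2 * s, loa_high = m + 2 * s,
       mean_pct_diff = sum(pct) / n)
}

oracle_paired_t <- function(d1, d2) {
  d <- d1 - d2
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tt <- m / (s / sqrt(n))
  list(t_stat = tt, p_two_sided = 2 * stats::pt(-abs(tt), df = n - 1))
}

# Brute-force E/A peak selection over a value window: enumerate all local
# maxima (plateaus collapse to their first sample), compute prominences by
# direct scanning, drop candidates below the prominence floor, and pick the
# two largest with (value, prominence, earlier-time) ranking.
oracle_peaks <- function(w, min_prominence_frac = 0.1) {
  n <- length(w)
  maxima <- integer(0)
  for (i in 2:(n - 1)) {
    if (w[i] <= w[i - 1]) next         # not the first sample of a rise/plateau
    j <- i
    while (j < n && w[j + 1] == w[i]) j <- j + 1
    if (j == n) next                   # plateau runs to the window edge
    if (w[j + 1] < w[i]) maxima <- c(maxima, i)
  }
  if (length(maxima) == 0) return(list(fused = TRUE))
  prom <- vapply(maxima, function(i) {
    lmin <- w[i]; j <- i - 1
    while (j >= 1 && w[j] <= w[i]) { lmin <- min(lmin, w[j]); j <- j - 1 }
    rmin <- w[i]; j <- i + 1
    while (j <= n && w[j] <= w[i]) { rmin <- min(rmin, w[j]); j <- j + 1 }
    w[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence_frac * max(w)
  maxima <- maxima[keep]; prom <- prom[keep]
  if (length(maxima) < 2) return(list(fused = TRUE))
  ord <- order(-w[maxima], -prom, maxima)
  two <- sort(maxima[ord[1:2]])
  list(fused = FALSE, e_index = two[1], a_index = two[2],
       e_value = w[two[1]], a_value = w[two[2]])
}
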
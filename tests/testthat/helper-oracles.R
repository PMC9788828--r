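# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Natural cubic spline by direct tridiagonal solve of the second-derivative
# system (M1 = Mn = 0), evaluated at `xout`.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, b)
  vapply(xout, function(t) {
    i <- findInterval(t, x, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    hi <- h[i]
    M[i] / (6 * hi) * (x[i + 1] - t)^3 + M[i + 1] / (6 * hi) * (t - x[i])^3 +
      (y[i] / hi - M[i] * hi / 6) * (x[i + 1] - t) +
      (y[i + 1] / hi - M[i + 1] * hi / 6) * (t - x[i])
  }, numeric(1))
}

# Exact two-tailed signed-rank p by enumeration of all 2^n sign patterns
# (requires distinct nonzero |d|).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  center <- n * (n + 1) / 4
  mean(abs(v_all - center) >= abs(v_obs - center) - 1e-9)
}

# Exact two-tailed rank-sum p by enumeration of all group labelings
# (requires distinct pooled values).
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  center <- n1 * n2 / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# Two-tailed Fisher p by direct hypergeometric summation over the support.
oracle_fisher_p <- function(g1, g2, g3, g4) {
  r1 <- g1 + g2; r2 <- g3 + g4; c1 <- g1 + g3
  supp <- max(0, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(supp, r1, r2, c1)
  p_obs <- stats::dhyper(g1, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Winsorized mean by explicit sort/cap with type-7 percentiles.
oracle_winsorized_mean <- function(v, cap) {
  lo <- stats::quantile(v, cap, type = 7, names = FALSE)
  hi <- stats::quantile(v, 1 - cap, type = 7, names = FALSE)
  mean(pmin(pmax(v, lo), hi))
}

# Centred moving average (even windows reach one frame further forward),
# NA outside complete windows -- direct windowed loop.
oracle_roll_mean <- function(v, w) {
  n <- length(v)
  back <- (w - 1) %/% 2
  fwd <- w - 1 - back
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- i - back; b <- i + fwd
    if (a >= 1 && b <= n) out[i] <- mean(v[a:b])
  }
  out
}
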
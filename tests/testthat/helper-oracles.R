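# Independent oracles, deliberately implemented by a different route than
# the package internals.

# Least-squares spectral power via lm(): 1 - SSR/SSR0 for the three-term
# floating-mean sinusoid fitted by R's own QR regression machinery.
oracle_power <- function(times, values, f) {
  s <- sin(2 * pi * f * times)
  co <- cos(2 * pi * f * times)
  fit <- stats::lm(values ~ s + co)
  1 - sum(stats::residuals(fit)^2) / sum((values - mean(values))^2)
}

# Coefficients (A, B, C) from the explicit 3x3 normal equations.
oracle_coefs <- function(times, values, f) {
  X <- cbind(sin(2 * pi * f * times), cos(2 * pi * f * times), 1)
  beta <- solve(crossprod(X), crossprod(X, values))
  c(A = beta[1L], B = beta[2L], C = beta[3L])
}

# Exact two-sided signed-rank p-value by literal enumeration of all 2^n
# sign assignments (doubling rule; zeros dropped).
oracle_signed_rank_p <- function(folds, mu = 1) {
  d <- folds - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
}

# Small random irregular series for property tests.
random_series <- function(n = 12L, span = 30) {
  t <- sort(stats::runif(n, 0, span))
  cycle_series(t, stats::rnorm(n, mean = 5))
}
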
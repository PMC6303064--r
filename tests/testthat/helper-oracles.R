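# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, for the statistics, R's htest wrappers):
# textbook formulas and brute-force loops only.

# Paired t by the textbook formula t = dbar / (s_d / sqrt(n)).
oracle_paired_t <- function(baseline, followup) {
  d <- followup - baseline
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1))
}

# Spearman rho from explicit average ranks + Pearson product-moment on the
# ranks; p via the t approximation.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

# OLS by the normal equations; returns coefficients, R^2, 95% CIs, p-values.
oracle_ols <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(crossprod(X1), crossprod(X1, y))
  fitted <- X1 %*% beta
  res <- y - fitted
  n <- length(y); p <- ncol(X1)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(s2 * solve(crossprod(X1))))
  tstat <- beta / se
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  tcrit <- qt(0.975, n - p)
  list(beta = drop(beta), se = se, r2 = r2,
       ci_low = drop(beta) - tcrit * se, ci_high = drop(beta) + tcrit * se,
       p = drop(2 * pt(-abs(tstat), n - p)))
}

# Forward SPGR signal evaluated independently (scalar, no package code).
oracle_forward <- function(t1, tr, flip_deg, k) {
  th <- flip_deg * pi / 180
  e1 <- exp(-tr / t1)
  k * (1 - e1) * sin(th) / (1 - e1 * cos(th))
}

# Bisection inversion of the forward equation.
oracle_invert_bisect <- function(s, tr, flip_deg, k,
                                 lo = 1, hi = 1e7, tol = 1e-10) {
  f <- function(t1) oracle_forward(t1, tr, flip_deg, k) - s
  uniroot(f, c(lo, hi), tol = tol)$root
}

# Small default-tissue phantom for mapping tests.
small_phantom <- function(shape = c(32, 32, 32), seed = 1, ...) {
  generate_phantom(phantom_spec(shape = shape, seed = seed, ...))
}

phantom_class_masks <- function(ph) {
  list(csf = ph$labels == 1L, gm = ph$labels == 2L,
       wm = ph$labels == 3L, lesion = ph$labels == 4L)
}
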
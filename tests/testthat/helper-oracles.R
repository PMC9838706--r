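# Independent oracles and small fixtures shared across tests.

# Literal normal-equations least squares (intercept prepended); solves
# (X'X) beta = X'y by explicit inversion -- deliberately a different code
# path from the package's QR-based fits.
ols_oracle <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  n <- length(y)
  s2 <- sum(resid^2) / (n - ncol(X))
  se <- sqrt(s2 * diag(solve(XtX)))
  list(beta = drop(beta), se = se, resid = drop(resid))
}

rlaplace <- function(n) (stats::rexp(n) - stats::rexp(n)) / sqrt(2)

# fixed 8-point mediation fixture (arbitrary but non-degenerate values)
fixture8 <- list(
  A = c(23, 31, 38, 47, 55, 64, 72, 86),
  B = c(1.62, 1.10, 1.41, 0.73, 0.95, 0.41, 0.68, -0.12),
  C = c(128, 103, 119, 98, 106, 87, 95, 70)
)

# small, fast simulation configs
tiny_config <- function(...) {
  sim_config(n_subjects = 80, grid_shape = c(6, 6, 4), smooth_fwhm = 4,
             missing_floor = 40, missing_prob = 0.3, ...)
}

# direct Moran's I computed with explicit loops over the proximity formula
morans_oracle <- function(values, coords) {
  n <- length(values)
  d <- as.matrix(dist(coords))
  W <- 1 - (d / max(d))^3
  diag(W) <- 0
  x <- values - mean(values)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * x[i] * x[j]
  (n / sum(W)) * num / sum(x^2)
}
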
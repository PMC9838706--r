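test_that("mediation fit matches the normal-equations oracle on the 8-point fixture", {
  f <- with(fixture8, fit_mediation(A, B, C))
  o1 <- with(fixture8, ols_oracle(C, cbind(A)))
  o2 <- with(fixture8, ols_oracle(C, cbind(B, A)))
  o3 <- with(fixture8, ols_oracle(B, cbind(A)))
  Ac <- fixture8$A - mean(fixture8$A)
  Bc <- fixture8$B - mean(fixture8$B)
  o4 <- ols_oracle(fixture8$C, cbind(Bc, Ac, Ac * Bc))
  expect_equal(f$c, unname(o1$beta[2]), tolerance = 1e-8)
  expect_equal(f$b, unname(o2$beta[2]), tolerance = 1e-8)
  expect_equal(f$c_prime, unname(o2$beta[3]), tolerance = 1e-8)
  expect_equal(f$a, unname(o3$beta[2]), tolerance = 1e-8)
  expect_equal(f$d, unname(o4$beta[4]), tolerance = 1e-8)
  expect_equal(f$se_b, unname(o2$se[2]), tolerance = 1e-8)
  expect_equal(f$se_a, unname(o3$se[2]), tolerance = 1e-8)
  expect_equal(f$ab, f$c - f$c_prime, tolerance = 1e-10)
})

test_that("null and near-noiseless mediators behave as expected", {
  set.seed(11)
  n <- 2000
  A <- runif(n, 20, 90)
  B <- rnorm(n)                       # independent of A and C
  C <- 120 - 0.7 * A + rnorm(n, sd = 12)
  f <- fit_mediation(A, B, C)
  expect_lt(abs(f$ab), 0.02)
  expect_equal(f$c_prime, f$c, tolerance = 0.05)

  # noiseless chain C = B = A (tiny jitter keeps the design full rank)
  set.seed(12)
  A <- runif(40, -1, 1)
  B <- A + rnorm(40, sd = 1e-4)
  C <- B
  f2 <- fit_mediation(A, B, C)
  expect_equal(f2$a, 1, tolerance = 1e-3)
  expect_equal(f2$b, 1, tolerance = 1e-3)
  expect_equal(f2$c, 1, tolerance = 1e-3)
  expect_equal(f2$c_prime, 0, tolerance = 1e-3)
  expect_equal(f2$ab, 1, tolerance = 1e-3)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_mediation(1:4, rnorm(4), rnorm(4)), "insufficient")
  expect_error(fit_mediation(rep(1, 10), rnorm(10), rnorm(10)), "constant")
  expect_error(fit_mediation(1:10, rep(2, 10), rnorm(10)), "constant")
  expect_error(fit_mediation(1:10, rnorm(10), rnorm(11)), "equal length")
})

test_that("directional b p-value halves, flips and matches a t-CDF oracle", {
  f <- with(fixture8, fit_mediation(A, B, C))
  # here a < 0 and b > 0: expected direction, p = upper tail of t
  oracle <- integrate(function(x) dt(x, f$df_b), f$t_b, Inf)$value
  expect_equal(f$p_b_directional, oracle, tolerance = 1e-4)
  expect_equal(f$p_b_directional, f$p_b / 2, tolerance = 1e-10)
  # wrong direction: same-sign a and b with a large |t| gives p near 1
  fw <- f; fw$t_b <- -f$t_b        # b now negative, like a
  expect_gt(directional_b_pvalue(fw), 0.99)
  # a exactly zero falls back to the two-tailed p, flagged
  fz <- f; fz$a <- 0
  pz <- directional_b_pvalue(fz)
  expect_true(isTRUE(attr(pz, "two_tailed")))
  expect_equal(as.numeric(pz), f$p_b, tolerance = 1e-12)
})

test_that("moderation screen passes most null replicates and applies both rules", {
  pass <- logical(200)
  set.seed(21)
  for (r in 1:200) {
    A <- runif(252, 20, 90)
    B <- -0.02 * A + rnorm(252, sd = 0.5)
    C <- 7.2 * B - 0.576 * A + rnorm(252, sd = 14)   # true d = 0
    pass[r] <- moderation_screen(fit_mediation(A, B, C))$pass
  }
  expect_gte(mean(pass), 0.9)
  # forced strong interaction fails the screen with reasons
  set.seed(22)
  A <- runif(252, 20, 90); B <- rnorm(252)
  C <- 5 * B - 0.5 * A + 0.3 * (A - mean(A)) * (B - mean(B)) + rnorm(252, sd = 5)
  scr <- moderation_screen(fit_mediation(A, B, C))
  expect_false(scr$pass)
  expect_gt(length(scr$reasons), 0)
})

test_that("indirect-effect identity and scale equivariance hold on fits and resamples", {
  set.seed(31)
  A <- runif(60, 20, 90)
  B <- -0.02 * A + rnorm(60, sd = 0.5)
  C <- 7 * B - 0.5 * A + rnorm(60, sd = 10)
  f <- fit_mediation(A, B, C)
  idx <- matrix(sample.int(60, 60 * 500, replace = TRUE), 60)
  bp <- voxmed:::boot_paths(A, B, C, idx)
  expect_lt(max(abs(bp$a * bp$b - (bp$c - bp$c_prime))), 1e-10)
  # closed-form resample paths agree with a full refit on one resample
  f1 <- fit_mediation(A[idx[, 1]], B[idx[, 1]], C[idx[, 1]])
  expect_equal(bp$a[1], f1$a, tolerance = 1e-10)
  expect_equal(bp$b[1], f1$b, tolerance = 1e-10)
  # scale equivariance: B -> k*B
  k <- 3.7
  fk <- fit_mediation(A, k * B, C)
  expect_equal(fk$a, k * f$a, tolerance = 1e-10)
  expect_equal(fk$b, f$b / k, tolerance = 1e-10)
  expect_equal(fk$ab, f$ab, tolerance = 1e-10)
  expect_equal(fk$c, f$c, tolerance = 1e-10)
  expect_equal(fk$c_prime, f$c_prime, tolerance = 1e-10)
})

test_that("BC interval reduces to the percentile interval for symmetric bootstraps", {
  est <- 1
  boot <- est + c(-(1:500), 1:500) / 100   # exactly symmetric about est
  ci <- voxmed:::bc_ci(boot, est)
  expect_equal(ci$z0, 0, tolerance = 1e-12)
  expect_equal(c(ci$lower, ci$upper),
               unname(quantile(boot, c(0.025, 0.975), type = 6)),
               tolerance = 1e-12)
})

test_that("BC bounds match an exhaustive resample-enumeration oracle at n = 5", {
  A <- c(25, 40, 52, 67, 81)
  B <- c(1.5, 1.1, 0.9, 0.5, 0.2)
  C <- c(118, 108, 100, 92, 80)
  est <- fit_mediation(A, B, C)$ab
  # all 5^5 ordered resamples
  grid <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5, 1:5))
  abv <- apply(grid, 1, function(ix) {
    if (var(A[ix]) == 0 || var(B[ix]) == 0) return(NA_real_)
    if (abs(cor(A[ix], B[ix])) > 1 - 1e-10) return(NA_real_)
    o3 <- ols_oracle(B[ix], cbind(A[ix]))
    o2 <- ols_oracle(C[ix], cbind(B[ix], A[ix]))
    unname(o3$beta[2] * o2$beta[2])
  })
  abv <- abv[!is.na(abv)]
  # oracle BC computation, step by step
  z0 <- qnorm(mean(abv < est))
  probs <- pnorm(c(2 * z0 - qnorm(0.975), 2 * z0 + qnorm(0.975)))
  srt <- sort(abv)
  N <- length(srt)
  lo_rng <- srt[c(max(1, floor(probs[1] * N) - 1), min(N, ceiling(probs[1] * N) + 1))]
  hi_rng <- srt[c(max(1, floor(probs[2] * N) - 1), min(N, ceiling(probs[2] * N) + 1))]
  ci <- voxmed:::bc_ci(abv, est)
  expect_equal(ci$z0, z0, tolerance = 1e-10)
  expect_gte(ci$lower, lo_rng[1]); expect_lte(ci$lower, lo_rng[2])
  expect_gte(ci$upper, hi_rng[1]); expect_lte(ci$upper, hi_rng[2])
})

test_that("bootstrap_ab resamples whole subjects and redraws degenerate resamples", {
  set.seed(41)
  A <- runif(40, 20, 90)
  B <- -0.02 * A + rnorm(40, sd = 0.5)
  C <- 7 * B - 0.5 * A + rnorm(40, sd = 10)
  bb <- bootstrap_ab(A, B, C, n_boot = 1000, seed = 7)
  expect_lt(bb$lower, bb$estimate)
  expect_gt(bb$upper, bb$estimate)
  expect_length(bb$boot, 1000)
  expect_error(bootstrap_ab(A, B, C, n_boot = 500), "at least 1000")
  # identical seed reproduces the interval
  bb2 <- bootstrap_ab(A, B, C, n_boot = 1000, seed = 7)
  expect_identical(bb$boot, bb2$boot)
})
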
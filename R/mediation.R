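# Internal OLS with conventional (homoscedastic) standard errors.
# Returns coefficients, SEs, two-tailed p, residuals, fitted, R2, df.
ols_fit <- function(y, X) {
  X <- cbind(`(Intercept)` = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("singular fit: design is rank-deficient in ", paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, y)
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  n <- length(y)
  k <- ncol(X)
  df <- n - k
  s2 <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(s2 * diag(XtXinv))
  names(se) <- names(coef)
  tval <- coef / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  list(coef = coef, se = se, t = tval, p = p, resid = resid, fitted = fitted,
       df = df, r2 = 1 - sum(resid^2) / tss, sigma2 = s2)
}

#' Fit the four-regression mediation system
#'
#' Fits, by ordinary least squares, the system relating a predictor (age,
#' `A`), a candidate mediator (`B`, e.g. a voxel or ROI BOLD contrast) and an
#' outcome (`C`, an IQ-like score):
#' \deqn{C = i_1 + cA + e_1}
#' \deqn{C = i_2 + bB + c'A + e_2}
#' \deqn{B = i_3 + aA + e_3}
#' \deqn{C = i_4 + bB + c'A + dAB + e_4}
#' The fourth equation screens for moderation of the direct effect by the
#' mediator; its product term is formed after mean-centering `A` and `B`,
#' which leaves the `d` test and its Cohen's f^2 unchanged while improving
#' conditioning. The indirect effect is `ab = a*b`, which for OLS on a common
#' sample is identical to `c - c'`.
#'
#' @param A,B,C numeric vectors of equal length (>= 5), no missing values.
#' @return An object of class `mediation_fit`: list with slopes `a`, `b`,
#'   `c`, `c_prime`, `d`, their standard errors (`se_*`) and two-tailed
#'   p-values (`p_*`), intercepts `i1`-`i4`, the indirect effect `ab`,
#'   the one-tailed `p_b_directional` (for `b` opposite in sign to `a`),
#'   the conjunction p-value `p_joint = max(p_a, p_b_directional)`,
#'   `f2_interaction` (Cohen's f^2 of the `d` term relative to equation 2),
#'   `n`, and residuals of equations 1-3 for diagnostics.
#' @examples
#' set.seed(1)
#' A <- runif(100, 20, 90)
#' B <- -0.02 * A + rnorm(100, sd = 0.4)
#' C <- 7 * B - 0.5 * A + rnorm(100, sd = 10)
#' f <- fit_mediation(A, B, C)
#' c(ab = f$ab, check = f$c - f$c_prime)
#' @export
fit_mediation <- function(A, B, C) {
  n <- length(A)
  if (length(B) != n || length(C) != n)
    stop("A, B and C must have equal length")
  if (n < 5) stop("insufficient data: need at least 5 subjects, got ", n)
  if (anyNA(A) || anyNA(B) || anyNA(C)) stop("missing values not allowed")
  near_const <- function(x) stats::sd(x) <= 1e-10 * (1 + max(abs(x)))
  if (near_const(A)) stop("singular fit: A is constant")
  if (near_const(B)) stop("singular fit: B is constant")

  eq1 <- ols_fit(C, cbind(A = A))
  eq2 <- ols_fit(C, cbind(B = B, A = A))
  eq3 <- ols_fit(B, cbind(A = A))
  Ac <- A - mean(A)
  Bc <- B - mean(B)
  eq4 <- ols_fit(C, cbind(B = Bc, A = Ac, AB = Ac * Bc))

  a <- unname(eq3$coef["A"]); b <- unname(eq2$coef["B"])
  fit <- list(
    a = a, se_a = unname(eq3$se["A"]), p_a = unname(eq3$p["A"]),
    b = b, se_b = unname(eq2$se["B"]), p_b = unname(eq2$p["B"]),
    c = unname(eq1$coef["A"]), se_c = unname(eq1$se["A"]), p_c = unname(eq1$p["A"]),
    c_prime = unname(eq2$coef["A"]), se_c_prime = unname(eq2$se["A"]),
    p_c_prime = unname(eq2$p["A"]),
    d = unname(eq4$coef["AB"]), se_d = unname(eq4$se["AB"]), p_d = unname(eq4$p["AB"]),
    i1 = unname(eq1$coef[1]), i2 = unname(eq2$coef[1]),
    i3 = unname(eq3$coef[1]), i4 = unname(eq4$coef[1]),
    ab = a * b, n = n,
    t_b = unname(eq2$t["B"]), df_b = eq2$df,
    f2_interaction = max(0, (eq4$r2 - eq2$r2) / (1 - eq4$r2)),
    r2_eq2 = eq2$r2, r2_eq4 = eq4$r2,
    residuals = list(eq1 = eq1$resid, eq2 = eq2$resid, eq3 = eq3$resid),
    fitted = list(eq1 = eq1$fitted, eq2 = eq2$fitted, eq3 = eq3$fitted)
  )
  fit$p_b_directional <- directional_b_pvalue(fit)
  fit$p_joint <- max(fit$p_a, fit$p_b_directional)
  class(fit) <- "mediation_fit"
  fit
}

#' One-tailed p-value that b opposes the sign of a
#'
#' Consistent mediation requires the indirect effect to share the sign of the
#' total effect; with a negative `a` (response declining with age) this means
#' a positive `b` (response predicting the outcome). The test is one-tailed
#' for `b` lying on the side of zero opposite to `sign(a)`. If `a` is exactly
#' zero the two-tailed p is returned with attribute `two_tailed = TRUE`.
#'
#' @param fit a `mediation_fit`.
#' @return the one-tailed probability (numeric scalar).
#' @export
directional_b_pvalue <- function(fit) {
  tb <- fit$t_b
  df <- fit$df_b
  if (fit$a == 0) {
    p <- 2 * stats::pt(abs(tb), df, lower.tail = FALSE)
    attr(p, "two_tailed") <- TRUE
    return(p)
  }
  # expected sign of b is the opposite of sign(a)
  if (fit$a < 0) stats::pt(tb, df, lower.tail = FALSE) else stats::pt(tb, df)
}

#' Moderation screen for the age-by-mediator interaction
#'
#' A voxel (or ROI) passes when the interaction term `d` of the fourth
#' equation is both small (Cohen's f^2 below `f2_max`) and nonsignificant
#' (two-tailed p above `p_min`, uncorrected). f^2 is the incremental
#' variance of the interaction relative to the no-interaction model:
#' (R2_full - R2_reduced) / (1 - R2_full).
#'
#' @param fit a `mediation_fit`.
#' @param f2_max effect-size ceiling (default 0.02, the "small" convention).
#' @param p_min significance floor (default 0.05, two-tailed, uncorrected).
#' @return list with logical `pass`, the `f2` and `p` used, and `reasons`
#'   (character, empty when passing).
#' @export
moderation_screen <- function(fit, f2_max = 0.02, p_min = 0.05) {
  if (fit$r2_eq4 >= 1 - 1e-12) stop("degenerate fit: R^2 of the interaction model is 1")
  reasons <- character(0)
  if (fit$f2_interaction >= f2_max)
    reasons <- c(reasons, sprintf("f2 = %.4f >= %.4f", fit$f2_interaction, f2_max))
  if (fit$p_d <= p_min)
    reasons <- c(reasons, sprintf("p = %.4f <= %.4f", fit$p_d, p_min))
  list(pass = length(reasons) == 0L, f2 = fit$f2_interaction, p = fit$p_d,
       reasons = reasons)
}

# Fast closed-form a, b, c, c' for case-resampled mediation fits.
# Columns of idx are resamples (indices into A/B/C).
boot_paths <- function(A, B, C, idx) {
  n <- nrow(idx)
  Am <- matrix(A[idx], n); Bm <- matrix(B[idx], n); Cm <- matrix(C[idx], n)
  sA <- colMeans(Am); sB <- colMeans(Bm); sC <- colMeans(Cm)
  Saa <- colMeans(Am * Am) - sA^2
  Sbb <- colMeans(Bm * Bm) - sB^2
  Sab <- colMeans(Am * Bm) - sA * sB
  Sac <- colMeans(Am * Cm) - sA * sC
  Sbc <- colMeans(Bm * Cm) - sB * sC
  a <- Sab / Saa
  det <- Sbb * Saa - Sab^2
  b <- (Sbc * Saa - Sab * Sac) / det
  c_prime <- (Sac * Sbb - Sab * Sbc) / det
  list(a = a, b = b, ab = a * b, c = Sac / Saa, c_prime = c_prime,
       degenerate = (Saa <= 0 | Sbb <= 0))
}

# Bias-corrected (no acceleration) percentile interval.
# z0 from the fraction of resamples strictly below the point estimate.
bc_ci <- function(boot, estimate, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  if (length(boot) == 0)
    return(list(lower = NA_real_, upper = NA_real_, z0 = NA_real_,
                probs = c(NA_real_, NA_real_)))
  frac <- mean(boot < estimate)
  # guard degenerate fractions (all resamples on one side)
  frac <- min(max(frac, 1 / (2 * length(boot))), 1 - 1 / (2 * length(boot)))
  z0 <- stats::qnorm(frac)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  ci <- unname(stats::quantile(boot, probs, type = 6))
  list(lower = ci[1], upper = ci[2], z0 = z0, probs = probs)
}

# Two-sided p-value by inversion of the BC interval: smallest alpha at which
# the interval excludes `null`.
bc_pvalue <- function(boot, estimate, null = 0) {
  boot <- boot[is.finite(boot)]
  eps <- 1 / (2 * length(boot))
  frac <- min(max(mean(boot < estimate), eps), 1 - eps)
  z0 <- stats::qnorm(frac)
  q0 <- min(max(mean(boot < null), eps), 1 - eps)
  zhat <- stats::qnorm(q0) - 2 * z0
  2 * min(stats::pnorm(zhat), 1 - stats::pnorm(zhat))
}

#' Bias-corrected bootstrap for the indirect effect
#'
#' Case (whole-subject) resampling with replacement; the full mediation
#' system is refitted on each resample and the indirect effect `ab`
#' recorded. The interval is the bias-corrected percentile interval (BC, no
#' acceleration): with `z0` the normal quantile of the fraction of resamples
#' below the point estimate, the bounds sit at the `pnorm(2*z0 -/+ z_(1-alpha/2))`
#' percentiles of the bootstrap distribution. Degenerate resamples (constant
#' `A` or `B`) are redrawn and counted; more than 1% redraws triggers a
#' warning.
#'
#' @param A,B,C numeric vectors as in [fit_mediation()].
#' @param n_boot number of resamples (default 15000).
#' @param seed integer seed for the resampling stream.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `lower`, `upper`, `z0`, `boot` (the
#'   bootstrap `ab` values), `p_value` (two-sided, by interval inversion)
#'   and `n_redrawn`.
#' @export
bootstrap_ab <- function(A, B, C, n_boot = 15000, seed = 1, conf = 0.95) {
  if (n_boot < 1000) stop("n_boot must be at least 1000")
  fit <- fit_mediation(A, B, C)
  n <- length(A)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n)
  paths <- boot_paths(A, B, C, idx)
  n_redrawn <- 0L
  while (any(paths$degenerate)) {
    bad <- which(paths$degenerate)
    n_redrawn <- n_redrawn + length(bad)
    idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE), n)
    repl <- boot_paths(A, B, C, idx2)
    for (f in c("a", "b", "ab", "c", "c_prime", "degenerate"))
      paths[[f]][bad] <- repl[[f]]
  }
  if (n_redrawn > 0.01 * n_boot)
    warning(sprintf("%d of %d resamples were degenerate and redrawn", n_redrawn, n_boot))
  ci <- bc_ci(paths$ab, fit$ab, conf)
  list(estimate = fit$ab, lower = ci$lower, upper = ci$upper, z0 = ci$z0,
       boot = paths$ab, p_value = bc_pvalue(paths$ab, fit$ab, 0),
       n_redrawn = n_redrawn, fit = fit)
}
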
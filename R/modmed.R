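# Edwards-Lambert moderated mediation: the moderator may enter every path;
# simple effects at +/- 1 SD; deltas of single and compound paths across
# 2 SDs, parametric tests for single paths and BC bootstrap for compound.

modmed_paths <- function(A, B, C, Z) {
  # re-center / re-standardize within the sample (full-refit semantics)
  Ac <- A - mean(A); Bc <- B - mean(B)
  Zs <- (Z - mean(Z)) / stats::sd(Z)
  X1 <- cbind(1, Ac, Zs, Ac * Zs)
  X2 <- cbind(1, Bc, Ac, Zs, Bc * Zs, Ac * Zs)
  f1 <- .lm.fit(X1, B)
  f2 <- .lm.fit(X2, C)
  c(a0 = f1$coefficients[2], az = f1$coefficients[4],
    b0 = f2$coefficients[2], cp0 = f2$coefficients[3],
    bz = f2$coefficients[5], cpz = f2$coefficients[6])
}

#' Fit an Edwards-Lambert moderated mediation model
#'
#' First stage: `B ~ A + Z + A:Z`; second stage:
#' `C ~ B + A + Z + B:Z + A:Z` (A and B mean-centered before products, Z
#' standardized). Simple path values `a(z)`, `b(z)`, `c'(z)`, `ab(z)` and
#' `total(z) = ab(z) + c'(z)` are evaluated at `z = -1, +1` SD, and each
#' delta is the change across those 2 SDs. Single-path deltas are tested
#' parametrically via the interaction coefficients; compound paths
#' (indirect `ab` and total effect) via bias-corrected percentile bootstrap
#' with p-values by interval inversion. Rows with missing values are
#' dropped listwise and the count reported.
#'
#' @param A,B,C numeric vectors (age, mediator, outcome).
#' @param Z moderator (may contain NA; listwise deletion).
#' @param n_boot bootstrap resamples for the compound paths (default 15000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `modmed_fit`: list with `simple` (data.frame of
#'   path values at z = -1, +1), `delta` (named vector: `a`, `b`, `c_prime`,
#'   `ab`, `total`), `p` (matching p-values), `ci_ab`, `ci_total`
#'   (BC bounds), `n` (rows used), `n_dropped`, and `boot`.
#' @export
fit_modmed <- function(A, B, C, Z, n_boot = 15000, seed = 1, conf = 0.95) {
  keep <- stats::complete.cases(A, B, C, Z)
  n_dropped <- sum(!keep)
  A <- A[keep]; B <- B[keep]; C <- C[keep]; Z <- Z[keep]
  n <- length(A)
  if (n < 20) stop("insufficient data after listwise deletion: n = ", n)
  if (stats::sd(Z) <= 1e-12 * (1 + max(abs(Z)))) stop("constant moderator")

  Ac <- A - mean(A); Bc <- B - mean(B)
  Zs <- (Z - mean(Z)) / stats::sd(Z)
  f1 <- ols_fit(B, cbind(A = Ac, Z = Zs, AZ = Ac * Zs))
  f2 <- ols_fit(C, cbind(B = Bc, A = Ac, Z = Zs, BZ = Bc * Zs, AZ = Ac * Zs))
  a0 <- unname(f1$coef["A"]); az <- unname(f1$coef["AZ"])
  b0 <- unname(f2$coef["B"]); cp0 <- unname(f2$coef["A"])
  bz <- unname(f2$coef["BZ"]); cpz <- unname(f2$coef["AZ"])

  zv <- c(-1, 1)
  simple <- data.frame(z = zv, a = a0 + az * zv, b = b0 + bz * zv,
                       c_prime = cp0 + cpz * zv)
  simple$ab <- simple$a * simple$b
  simple$total <- simple$ab + simple$c_prime
  delta <- c(a = 2 * az, b = 2 * bz, c_prime = 2 * cpz,
             ab = simple$ab[2] - simple$ab[1],
             total = simple$total[2] - simple$total[1])

  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n)
  boot <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("ab", "total")))
  for (b in seq_len(n_boot)) {
    i <- idx[, b]
    if (stats::sd(Z[i]) == 0 || stats::sd(A[i]) == 0 || stats::sd(B[i]) == 0) {
      i <- sample.int(n, n, replace = TRUE)
    }
    p <- modmed_paths(A[i], B[i], C[i], Z[i])
    d_ab <- (p["a0"] + p["az"]) * (p["b0"] + p["bz"]) -
            (p["a0"] - p["az"]) * (p["b0"] - p["bz"])
    boot[b, ] <- c(d_ab, d_ab + 2 * p["cpz"])
  }
  ci_ab <- bc_ci(boot[, "ab"], delta["ab"], conf)
  ci_total <- bc_ci(boot[, "total"], delta["total"], conf)
  p <- c(a = unname(f1$p["AZ"]), b = unname(f2$p["BZ"]),
         c_prime = unname(f2$p["AZ"]),
         ab = bc_pvalue(boot[, "ab"], delta["ab"]),
         total = bc_pvalue(boot[, "total"], delta["total"]))
  structure(list(simple = simple, delta = delta, p = p,
                 ci_ab = ci_ab[c("lower", "upper")],
                 ci_total = ci_total[c("lower", "upper")],
                 stage1 = f1, stage2 = f2, n = n, n_dropped = n_dropped,
                 boot = boot),
            class = "modmed_fit")
}

#' Residualize a moderator on other moderators
#'
#' OLS residual of the target on the other columns plus an intercept,
#' re-standardized to mean 0, SD 1. With no other columns, returns the
#' standardized target.
#'
#' @param Z_target numeric vector.
#' @param Z_others numeric matrix/data.frame (or NULL / zero columns).
#' @return standardized residual vector.
#' @export
residualize_moderators <- function(Z_target, Z_others = NULL) {
  if (is.null(Z_others) || NCOL(Z_others) == 0 || length(Z_others) == 0) {
    s <- stats::sd(Z_target)
    if (s == 0) stop("constant moderator")
    return((Z_target - mean(Z_target)) / s)
  }
  Zo <- as.matrix(Z_others)
  if (nrow(Zo) != length(Z_target)) stop("moderators not aligned")
  X <- cbind(1, Zo)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(Zo)[qx$pivot[(qx$rank + 1):ncol(X)] - 1]
    stop("collinear moderators: ", paste(bad, collapse = ", "))
  }
  r <- qr.resid(qx, Z_target)
  s <- stats::sd(r)
  if (s <= 1e-12 * (1 + max(abs(Z_target))))
    return(r)  # target in span of the others: zero residual, caller errors downstream
  (r - mean(r)) / s
}

#' Moderated-mediation table across several moderators
#'
#' One row per moderator: deltas across 2 SDs for each single and compound
#' path with their p-values and the N used (listwise per moderator). With
#' `residualize = TRUE` each moderator is first residualized on the others.
#'
#' @param A,B,C numeric vectors.
#' @param Z data.frame of moderator columns.
#' @param residualize residualize each moderator on the others first.
#' @inheritParams fit_modmed
#' @return data.frame shaped like a moderated-mediation results table.
#' @export
modmed_table <- function(A, B, C, Z, n_boot = 5000, seed = 1, residualize = FALSE) {
  rows <- lapply(seq_along(Z), function(j) {
    zj <- Z[[j]]
    if (residualize && length(Z) > 1) {
      cc <- stats::complete.cases(Z)
      zr <- rep(NA_real_, length(zj))
      zr[cc] <- residualize_moderators(zj[cc], as.matrix(Z[cc, -j, drop = FALSE]))
      zj <- zr
    }
    f <- fit_modmed(A, B, C, zj, n_boot = n_boot, seed = seed + j)
    data.frame(moderator = names(Z)[j], n = f$n,
               delta_a = f$delta["a"], p_a = f$p["a"],
               delta_b = f$delta["b"], p_b = f$p["b"],
               delta_c_prime = f$delta["c_prime"], p_c_prime = f$p["c_prime"],
               delta_ab = f$delta["ab"], p_ab = f$p["ab"],
               delta_total = f$delta["total"], p_total = f$p["total"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
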
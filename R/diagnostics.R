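# Regression diagnostics and covariate controls: RESET specification test,
# White/Wooldridge heteroscedasticity test, latent-score construction,
# framewise-displacement summaries and global residualization.

#' Ramsey RESET specification test
#'
#' Fits `y` on the design (plus intercept), augments the design with the
#' 2nd-4th powers of the standardized fitted values, and F-tests the three
#' added terms. A significant result indicates that nonlinear functions of
#' the predictors are needed (functional-form misspecification).
#'
#' @param y response vector.
#' @param design numeric matrix/vector of predictors (no intercept column).
#' @return list with `statistic` (F), `df` (c(3, n - k - 4) with k
#'   predictors), and `p`.
#' @export
reset_test <- function(y, design) {
  X <- as.matrix(design)
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 4) stop("insufficient data for the RESET test")
  base <- ols_fit(y, X)
  fh <- (base$fitted - mean(base$fitted)) / stats::sd(base$fitted)
  Xa <- cbind(X, f2 = fh^2, f3 = fh^3, f4 = fh^4)
  qa <- qr(cbind(1, Xa))
  if (qa$rank < ncol(Xa) + 1) stop("augmented design is rank-deficient")
  aug <- ols_fit(y, Xa)
  df2 <- n - k - 4
  rss0 <- sum(base$resid^2); rss1 <- sum(aug$resid^2)
  f <- ((rss0 - rss1) / 3) / (rss1 / df2)
  list(statistic = f, df = c(3, df2), p = stats::pf(f, 3, df2, lower.tail = FALSE))
}

#' White/Wooldridge heteroscedasticity test
#'
#' Wooldridge's two-degree-of-freedom version of the White test: squared
#' residuals are regressed on the fitted values and their squares, and the
#' LM statistic `n * R^2` of that auxiliary regression is referred to
#' chi-squared with 2 df.
#'
#' @param residuals,fitted residuals and fitted values of an OLS fit.
#' @return list with `statistic` (chi-squared), `df` (2), `p`.
#' @export
white_wooldridge_test <- function(residuals, fitted) {
  if (stats::sd(fitted) == 0) stop("constant fitted values")
  aux <- ols_fit(residuals^2, cbind(f = fitted, f2 = fitted^2))
  stat <- length(residuals) * aux$r2
  list(statistic = stat, df = 2, p = stats::pchisq(stat, 2, lower.tail = FALSE))
}

#' Diagnostic report for a mediation fit
#'
#' Runs the RESET and White/Wooldridge tests on each of the first three
#' mediation equations.
#'
#' @param fit a `mediation_fit`.
#' @param A,B,C the data the fit came from.
#' @return nested list keyed by equation (`eq1`, `eq2`, `eq3`), each with
#'   `reset` and `white` entries.
#' @export
diagnostic_report <- function(fit, A, B, C) {
  designs <- list(eq1 = list(y = C, X = cbind(A = A)),
                  eq2 = list(y = C, X = cbind(B = B, A = A)),
                  eq3 = list(y = B, X = cbind(A = A)))
  lapply(designs, function(d) {
    base <- ols_fit(d$y, d$X)
    list(reset = reset_test(d$y, d$X),
         white = white_wooldridge_test(base$resid, base$fitted))
  })
}

#' Latent score from a subtest matrix
#'
#' First principal component of the column-standardized subtest matrix,
#' sign-fixed to correlate positively with the subtest sum and affinely
#' rescaled to a target mean and SD. Used to build a homoscedastic latent
#' IQ variable from raw subtest scores.
#'
#' @param subtest_matrix numeric matrix (subjects x subtests, >= 2 columns,
#'   complete).
#' @param target_mean,target_sd scale of the returned score.
#' @return numeric per-subject score with attribute `loadings`.
#' @export
latent_score <- function(subtest_matrix, target_mean = 100, target_sd = 15) {
  X <- as.matrix(subtest_matrix)
  if (ncol(X) < 2) stop("need at least 2 subtests")
  if (anyNA(X)) stop("subtest matrix must be complete")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant subtest column: ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- scale(X)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  v <- eg$vectors[, 1]
  score <- drop(Xs %*% v)
  if (stats::cor(score, rowSums(Xs)) < 0) { v <- -v; score <- -score }
  score <- (score - mean(score)) / stats::sd(score) * target_sd + target_mean
  attr(score, "loadings") <- v
  score
}

#' Framewise displacement summaries from motion parameters
#'
#' Per frame transition, FD is the sum of absolute translation increments
#' plus `radius_mm` times the sum of absolute rotation increments (rotations
#' projected onto a sphere surface). Returns the mean FD over transitions
#' and the proportion of transitions exceeding the high-motion threshold.
#'
#' @param motion_params matrix with one row per frame and 6 columns: three
#'   translations (mm) then three rotations (radians).
#' @param radius_mm rotation projection radius (default 50).
#' @param threshold_mm high-motion threshold (default 0.9).
#' @return list with `mean_fd` and `prop_high`.
#' @export
fd_summaries <- function(motion_params, radius_mm = 50, threshold_mm = 0.9) {
  M <- as.matrix(motion_params)
  if (ncol(M) != 6) stop("format error: motion parameters need 6 columns")
  if (nrow(M) < 2) stop("need at least 2 frames")
  d <- abs(diff(M))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE])
  list(mean_fd = mean(fd), prop_high = mean(fd > threshold_mm))
}

#' Residualize key variables on nuisance covariates
#'
#' Replaces age, outcome and moderator columns of the cohort, and every
#' voxel of the stack, by their OLS residuals on the named covariate columns
#' plus an intercept (per-voxel residualization uses only that voxel's
#' available subjects). Used as a head-motion control: all analyses can be
#' repeated on the residualized data.
#'
#' @param cohort a `cohort_table`.
#' @param stack an aligned `voxel_stack` (or NULL).
#' @param covariates character, names of covariate columns in `cohort`
#'   (default the motion summaries).
#' @return list with residualized `cohort` and `stack`.
#' @export
residualize_all <- function(cohort, stack = NULL,
                            covariates = c("motion_mean_fd", "motion_prop_high")) {
  if (!all(covariates %in% names(cohort)))
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(cohort)), collapse = ", "))
  Xc <- as.matrix(cohort[, covariates, drop = FALSE])
  if (anyNA(Xc)) stop("covariates must be complete")
  qx <- qr(cbind(1, Xc))
  if (qx$rank < ncol(Xc) + 1)
    stop("collinear covariates: ", paste(covariates, collapse = ", "))
  keyvars <- setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)], covariates)
  for (v in keyvars) cohort[[v]] <- qr.resid(qx, cohort[[v]])
  if (!is.null(stack)) {
    check_alignment_n(stack, nrow(cohort))
    for (j in seq_len(ncol(stack$values))) {
      ok <- stack$mask[, j]
      if (sum(ok) > ncol(Xc) + 1) {
        qv <- qr(cbind(1, Xc[ok, , drop = FALSE]))
        stack$values[ok, j] <- qr.resid(qv, stack$values[ok, j])
      }
    }
  }
  list(cohort = cohort, stack = stack)
}

check_alignment_n <- function(stack, n) {
  if (nrow(stack$values) != n)
    stop("alignment error: stack has ", nrow(stack$values), " subjects, expected ", n)
}
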
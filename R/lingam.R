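# ICA-LiNGAM causal-direction estimation. The linear non-Gaussian acyclic
# model X = BX + E is identified from observational data by ICA when at most
# one error term is Gaussian: the ICA unmixing matrix equals (I - B) up to
# row permutation and scaling, fixed by diagonal dominance and the
# requirement that B be permutable to strict lower-triangular form.

# Fixed-point negentropy ICA (tanh contrast, symmetric decorrelation).
# X must be centered. Returns the unmixing matrix W (sources = X %*% t(W))
# or NULL on non-convergence.
fast_ica <- function(X, tol = 1e-8, maxit = 1000, seed = 1) {
  n <- nrow(X); p <- ncol(X)
  cv <- crossprod(X) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values)) stop("singular data covariance")
  K <- diag(1 / sqrt(eg$values), p) %*% t(eg$vectors)    # whitening
  Z <- X %*% t(K)
  sym_orth <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), p) %*% t(e$vectors) %*% W
  }
  set.seed(seed)
  W <- sym_orth(matrix(stats::rnorm(p * p), p, p))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    WX <- Z %*% t(W)            # n x p projections
    G <- tanh(WX)
    W_new <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), p) %*% W
    W_new <- sym_orth(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) return(NULL)
  list(W = W %*% K, Z = Z, Wrot = W)
}

# negentropy proxy of extracted sources (higher = more non-Gaussian)
negentropy_score <- function(Z, Wrot) {
  S <- Z %*% t(Wrot)
  g0 <- 0.3745672  # E[log cosh(nu)], nu standard normal
  sum((colMeans(log(cosh(S))) - g0)^2)
}

all_perms <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (p in all_perms(m - 1)) for (k in seq_len(m))
    out[[length(out) + 1L]] <- append(p, m, after = k - 1L)
  out
}

#' Fit a LiNGAM causal model
#'
#' Columns are standardized internally (the estimator is not scale
#' invariant). ICA (fixed-point, tanh contrast, deflation) is run with up to
#' `restarts` seeded restarts and the converged run with the highest
#' negentropy kept. The unmixing rows are permuted to maximize diagonal
#' dominance (minimize the sum of reciprocal absolute diagonal entries,
#' exhaustively for up to 6 variables), rescaled to a unit diagonal, and
#' `B = I - W` formed. The causal order is found by zeroing the
#' `m(m+1)/2` smallest-magnitude entries of `B` (after treating entries
#' below `prune_tol` as structural zeros) and searching permutations for
#' strict lower-triangularity, zeroing further entries one at a time if
#' needed; needing extra zeroing raises the `not_triangular` flag. Final
#' connection strengths are re-estimated by least squares given the causal
#' order (each variable on its predecessors, standardized data), so the
#' returned matrix is zero outside the causal lower triangle (acyclicity).
#'
#' @param X numeric matrix (subjects x variables), at least 10 rows per
#'   column recommended.
#' @param seed integer seed for the ICA restarts.
#' @param restarts number of seeded ICA restarts (default 5).
#' @param prune_tol entries below this magnitude are structural zeros.
#' @return object of class `direction_estimate`: list with `B` (coefficient
#'   matrix under the causal order, strictly lower-triangular up to
#'   permutation), `B_raw` (before acyclicity enforcement), `order`
#'   (causal order, earliest cause first), `not_triangular`,
#'   `converged`, `seeds_tried`, and `variables`.
#' @export
lingam_fit <- function(X, seed = 1, restarts = 5, prune_tol = 1e-3) {
  X <- as.matrix(X)
  m <- ncol(X)
  if (m < 2) stop("need at least 2 variables")
  if (m > 6) stop("exhaustive permutation search limited to 6 variables")
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(m))
  Xs <- scale(X)
  best <- NULL; best_score <- -Inf
  seeds <- seed + seq_len(restarts) - 1L
  for (s in seeds) {
    ic <- fast_ica(Xs, seed = s)
    if (is.null(ic)) next
    sc <- negentropy_score(ic$Z, ic$Wrot)
    if (sc > best_score) { best <- ic; best_score <- sc }
  }
  if (is.null(best))
    stop("ICA failed to converge after restarts with seeds ",
         paste(seeds, collapse = ", "))
  W <- best$W
  perms <- all_perms(m)
  cost <- vapply(perms, function(p) sum(1 / pmax(abs(diag(W[p, , drop = FALSE])), 1e-12)), 0)
  W1 <- W[perms[[which.min(cost)]], , drop = FALSE]
  W2 <- W1 / diag(W1)
  B <- diag(m) - W2

  # causal order by pruning
  Bp <- B
  Bp[abs(Bp) < prune_tol] <- 0
  av <- sort(abs(Bp[abs(Bp) > 0]))
  k <- max(0L, m * (m + 1) / 2 - sum(Bp == 0))
  if (k > 0) Bp[abs(Bp) <= av[k] & Bp != 0] <- 0
  find_order <- function(Bz) {
    for (p in perms) {
      Bq <- Bz[p, p, drop = FALSE]
      if (all(Bq[upper.tri(Bq, diag = TRUE)] == 0)) return(p)
    }
    NULL
  }
  not_triangular <- FALSE
  ord <- find_order(Bp)
  while (is.null(ord)) {
    not_triangular <- TRUE
    rem <- abs(Bp[Bp != 0])
    if (length(rem) == 0) { ord <- seq_len(m); break }
    Bp[abs(Bp) == min(rem) & Bp != 0] <- 0
    ord <- find_order(Bp)
  }
  ord <- as.integer(ord)
  pos <- order(ord)   # pos[v] = position of variable v in the causal order
  # final connection strengths: least squares given the causal order
  # (each variable regressed on all its predecessors, standardized data)
  B_final <- matrix(0, m, m)
  for (k in 2:m) {
    v <- ord[k]
    preds <- ord[seq_len(k - 1)]
    cf <- stats::lm.fit(cbind(1, Xs[, preds, drop = FALSE]), Xs[, v])$coefficients
    B_final[v, preds] <- cf[-1]
  }
  dimnames(B_final) <- dimnames(B) <- list(vars, vars)
  structure(list(B = B_final, B_raw = B, order = ord, variables = vars,
                 not_triangular = not_triangular, converged = TRUE,
                 seeds_tried = seeds, negentropy = best_score),
            class = "direction_estimate")
}

# default hypothesized edges for (age, mediator, outcome): 1->2, 1->3, 2->3
default_hypotheses <- function(m) {
  if (m != 3) stop("supply `hypotheses` explicitly for other than 3 variables")
  matrix(c(1L, 2L, 1L, 3L, 2L, 3L), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("from", "to")))
}

#' Per-pair directionality scores
#'
#' For each hypothesized edge `from -> to`, the score is the absolute
#' estimated coefficient in the hypothesized direction minus the absolute
#' coefficient in the reverse direction (of which only one is nonzero under
#' acyclicity); positive values support the hypothesized direction.
#'
#' @param est a `direction_estimate`.
#' @param hypotheses 2-column integer matrix of `(from, to)` pairs; default
#'   is the chain-plus-direct layout for 3 variables
#'   (1->2, 1->3, 2->3).
#' @return named numeric vector of scores.
#' @export
direction_scores <- function(est, hypotheses = NULL) {
  if (is.null(hypotheses)) hypotheses <- default_hypotheses(length(est$variables))
  s <- apply(hypotheses, 1, function(h)
    abs(est$B[h[2], h[1]]) - abs(est$B[h[1], h[2]]))
  names(s) <- apply(hypotheses, 1, function(h)
    paste0(est$variables[h[1]], "->", est$variables[h[2]]))
  s
}

# the "undirected" coefficient of each pair: whichever of the two directed
# coefficients is nonzero (0 if both are)
undirected_coefs <- function(est, hypotheses) {
  apply(hypotheses, 1, function(h) {
    lo <- est$B[h[2], h[1]]; hi <- est$B[h[1], h[2]]
    if (abs(lo) >= abs(hi)) lo else hi
  })
}

#' Cluster bootstrap for causal directionality
#'
#' The mediating voxels are split into clusters (e.g. by
#' [watershed_partition()]); per bootstrap resample of subjects, LiNGAM is
#' fitted to (age, cluster-mean mediator, outcome) for every cluster,
#' clusters are discarded when the sign of any undirected coefficient
#' differs from the all-voxel reference or the coefficient matrix could not
#' be permuted to lower-triangular form, and the per-pair directionality
#' scores are averaged over retained clusters. Bias-corrected percentile
#' intervals are formed over resamples. "Undirected coefficient" is read as
#' the nonzero one of each pair's two directed coefficients.
#'
#' @param cohort a `cohort_table`.
#' @param stack an aligned `voxel_stack`.
#' @param cluster_labels integer vector over the stack's retained voxels (or
#'   a 3-D label array on the stack grid); label 0 = unclustered.
#' @param reference a `direction_estimate` fitted to the all-voxel summary
#'   mediator.
#' @param n_boot resamples (default 15000).
#' @param seed integer seed.
#' @param hypotheses as in [direction_scores()].
#' @param restarts ICA restarts per cluster fit (default 2; the reference
#'   fit should use more).
#' @param conf confidence level (default 0.95).
#' @return list with `estimate` (cluster-mean scores on the original
#'   sample), `ci` (per-pair BC bounds), `boot` (resamples x pairs),
#'   `discard_rate` (mean fraction discarded, by reason), `missing_fraction`
#'   (resamples with no retained cluster), and metadata.
#' @export
cluster_bootstrap_direction <- function(cohort, stack, cluster_labels, reference,
                                        n_boot = 15000, seed = 1,
                                        hypotheses = NULL, restarts = 2,
                                        conf = 0.95) {
  check_alignment(cohort, stack)
  if (is.array(cluster_labels)) cluster_labels <- as.vector(cluster_labels)[stack$keep]
  if (length(cluster_labels) != ncol(stack$values))
    stop("cluster labels not aligned with the stack voxels")
  if (is.null(hypotheses)) hypotheses <- default_hypotheses(3)
  ref_signs <- sign(undirected_coefs(reference, hypotheses))
  ids <- sort(unique(cluster_labels[cluster_labels > 0]))
  series <- vapply(ids, function(k)
    summary_series(stack, which(cluster_labels == k)), numeric(nrow(cohort)))
  n <- nrow(cohort)
  npair <- nrow(hypotheses)

  eval_sample <- function(idx, seed0) {
    scores <- matrix(NA_real_, length(ids), npair)
    reason <- character(length(ids))
    for (k in seq_along(ids)) {
      X <- cbind(A = cohort$A[idx], M = series[idx, k], C = cohort$C[idx])
      est <- tryCatch(lingam_fit(X, seed = seed0 + k, restarts = restarts),
                      error = function(e) NULL)
      if (is.null(est)) { reason[k] <- "nonconvergence"; next }
      if (est$not_triangular) { reason[k] <- "not_triangular"; next }
      if (any(sign(undirected_coefs(est, hypotheses)) != ref_signs)) {
        reason[k] <- "sign_mismatch"; next
      }
      scores[k, ] <- direction_scores(est, hypotheses)
    }
    list(mean = colMeans(scores, na.rm = TRUE), reason = reason,
         n_kept = sum(!is.na(scores[, 1])))
  }

  point <- eval_sample(seq_len(n), seed)
  set.seed(seed)
  idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), n)
  boot <- matrix(NA_real_, n_boot, npair)
  reasons <- c(sign_mismatch = 0, not_triangular = 0, nonconvergence = 0)
  n_missing <- 0L
  for (b in seq_len(n_boot)) {
    r <- eval_sample(idx_mat[, b], seed + b * 101L)
    if (r$n_kept == 0L) { n_missing <- n_missing + 1L; next }
    boot[b, ] <- r$mean
    tb <- table(r$reason[nzchar(r$reason)])
    for (nm in names(tb)) reasons[nm] <- reasons[nm] + tb[[nm]]
  }
  if (n_missing > 0.5 * n_boot)
    warning("more than half of bootstrap resamples retained no cluster")
  ci <- t(vapply(seq_len(npair), function(j) {
    bj <- boot[, j][!is.na(boot[, j])]
    unlist(bc_ci(bj, point$mean[j], conf)[c("lower", "upper")])
  }, numeric(2)))
  nm <- apply(hypotheses, 1, function(h)
    paste0(reference$variables[h[1]], "->", reference$variables[h[2]]))
  rownames(ci) <- nm; colnames(boot) <- nm
  est <- point$mean; names(est) <- nm
  list(estimate = est, ci = ci, boot = boot,
       discard_rate = reasons / (length(ids) * n_boot),
       missing_fraction = n_missing / n_boot, n_clusters = length(ids),
       clusters_kept_observed = point$n_kept,
       undirected_reading = "nonzero directed coefficient of each pair")
}
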
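# LOVE (left-out variables error) sensitivity analysis: how strong an
# unmodeled confounder of the mediator-outcome relation would have to be to
# fully account for the observed mediation.

#' LOVE sensitivity surface for the indirect effect
#'
#' For each hypothetical confounder `U` with correlations `r_UM` (with the
#' mediator) and `r_UY` (with the outcome) - by default partial correlations
#' given age, since age is treated as exogenous - the mediator-to-outcome
#' path is recomputed by omitted-variable algebra:
#' `b_adj = (rho - r_UM * r_UY) / (1 - r_UM^2) * sd(C|A)/sd(M|A)`, with
#' `rho` the observed age-partialled mediator-outcome correlation. The
#' adjusted indirect effect is `ab_adj = a * b_adj`; it equals the result
#' of refitting the second equation with `U` explicitly included as a
#' covariate having the stated correlations. Grid points whose implied
#' (U, M, C) correlation matrix is not positive definite are flagged
#' infeasible and excluded from the zero contour.
#'
#' @param fit a `mediation_fit` from the same data.
#' @param A,B,C the data the fit came from.
#' @param grid numeric vector of correlation values for both axes
#'   (default 101 points over `[-0.9, 0.9]`).
#' @param partial interpret the confounder correlations given age (default
#'   TRUE) or marginally.
#' @return object of class `sensitivity_surface`: list with `r_um`, `r_uy`
#'   (the grid), matrix `ab_adj` (rows = r_UM), logical `feasible`,
#'   `contour` (two-column matrix of interpolated zero crossings), and the
#'   observed `rho`, `a` and scale factor.
#' @export
love_surface <- function(fit, A, B, C, grid = seq(-0.9, 0.9, length.out = 101),
                         partial = TRUE) {
  stopifnot(inherits(fit, "mediation_fit"))
  if (any(abs(grid) >= 1)) stop("grid must lie within (-1, 1)")
  if (partial) {
    m_r <- stats::residuals(stats::lm(B ~ A))
    c_r <- stats::residuals(stats::lm(C ~ A))
  } else {
    m_r <- B - mean(B); c_r <- C - mean(C)
  }
  rho <- stats::cor(m_r, c_r)
  k <- stats::sd(c_r) / stats::sd(m_r)
  prod_grid <- outer(grid, grid)
  b_adj <- (rho - prod_grid) / (1 - grid^2) * k   # rows index r_UM
  ab_adj <- fit$a * b_adj
  feasible <- (1 + 2 * prod_grid * rho - outer(grid^2, grid^2, "+") - rho^2) > 0
  ab_na <- ab_adj
  ab_na[!feasible] <- NA
  # zero contour by sign-change interpolation along each r_UM row
  pts <- list()
  for (i in seq_along(grid)) {
    row <- ab_na[i, ]
    s <- sign(row)
    ch <- which(!is.na(s[-length(s)]) & !is.na(s[-1]) & s[-length(s)] * s[-1] < 0)
    for (j in ch) {
      t0 <- row[j] / (row[j] - row[j + 1])
      pts[[length(pts) + 1L]] <- c(grid[i], grid[j] + t0 * (grid[j + 1] - grid[j]))
    }
    z <- which(!is.na(row) & row == 0)
    for (j in z) pts[[length(pts) + 1L]] <- c(grid[i], grid[j])
  }
  contour <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 2)
  colnames(contour) <- c("r_um", "r_uy")
  structure(list(r_um = grid, r_uy = grid, ab_adj = ab_adj, feasible = feasible,
                 contour = contour, rho = rho, a = fit$a, scale = k,
                 ab = fit$ab, partial = partial),
            class = "sensitivity_surface")
}

#' Adjusted indirect effect at an arbitrary confounder-correlation point
#'
#' Evaluates the LOVE adjustment off the grid, using the surface's stored
#' observed quantities: `ab_adj = a * (rho - r_um*r_uy) / (1 - r_um^2) *
#' sd(C|A)/sd(M|A)`. Infeasible points return NA.
#'
#' @param surface a `sensitivity_surface`.
#' @param r_um,r_uy confounder correlations (|r| < 1).
#' @return the adjusted indirect effect (numeric scalar, NA if infeasible).
#' @export
ab_adjusted <- function(surface, r_um, r_uy) {
  if (abs(r_um) >= 1 || abs(r_uy) >= 1) stop("correlations must lie in (-1, 1)")
  rho <- surface$rho
  if (1 + 2 * r_um * r_uy * rho - r_um^2 - r_uy^2 - rho^2 <= 0) return(NA_real_)
  surface$a * (rho - r_um * r_uy) / (1 - r_um^2) * surface$scale
}

#' Confounding threshold from a sensitivity surface
#'
#' Walks the surface's matched diagonal - `r_UM = r_UY` when the observed
#' age-partialled mediator-outcome correlation is positive, `r_UM = -r_UY`
#' when it is negative, so the confounder acts in the direction that can
#' explain the observed association - outward from the origin, and locates
#' the first sign change of the adjusted indirect effect by linear
#' interpolation. Also reports the smallest single-coordinate magnitude
#' attained on the zero contour (the paper-style "at least one correlation
#' must exceed" summary, computed as the minimum over contour points of the
#' larger coordinate) and the corresponding minimum average.
#'
#' @param surface a `sensitivity_surface`.
#' @return list with `r_star` (diagonal threshold; NA with
#'   `beyond_grid = TRUE` when no sign change occurs within the grid),
#'   `min_single` and `min_average`.
#' @export
confounding_threshold <- function(surface) {
  if (surface$ab == 0)
    return(list(r_star = 0, beyond_grid = FALSE, min_single = 0, min_average = 0))
  sgn <- if (surface$rho >= 0) 1 else -1
  rr <- surface$r_um[surface$r_um >= 0]
  diag_vals <- vapply(rr, function(r) {
    i <- which.min(abs(surface$r_um - r))
    j <- which.min(abs(surface$r_uy - sgn * r))
    if (!surface$feasible[i, j]) NA_real_ else surface$ab_adj[i, j]
  }, 0)
  s <- sign(diag_vals)
  ch <- which(!is.na(s[-length(s)]) & !is.na(s[-1]) & s[-length(s)] * s[-1] < 0)
  if (length(ch) == 0) {
    r_star <- NA_real_; beyond <- TRUE
  } else {
    j <- ch[1]
    t0 <- diag_vals[j] / (diag_vals[j] - diag_vals[j + 1])
    r_star <- rr[j] + t0 * (rr[j + 1] - rr[j])
    beyond <- FALSE
  }
  if (nrow(surface$contour) > 0) {
    am <- abs(surface$contour)
    min_single <- min(pmax(am[, 1], am[, 2]))
    min_average <- min(rowMeans(am))
  } else min_single <- min_average <- NA_real_
  list(r_star = r_star, beyond_grid = beyond,
       min_single = min_single, min_average = min_average)
}
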
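# Spatial-autocorrelation-aware inference on voxel statistic maps:
# Moran eigenvector spectral randomization (MSR) and watershed partitioning.

#' Build a Moran eigenvector basis from voxel coordinates
#'
#' The proximity of two voxels is `1 - (d/d_max)^3` (zero on the diagonal),
#' with `d` the Euclidean distance in world mm. The proximity matrix is
#' doubly centered and eigendecomposed; the full spectrum is retained. The
#' eigenvectors describe the map's spatial autocorrelation structure at all
#' scales and are the randomization basis for surrogate maps. Voxel sets
#' larger than `max_voxels` are randomly subsampled (dense eigendecomposition
#' cost) and the subsample recorded.
#'
#' @param coords numeric matrix, voxels x dimensions (world mm).
#' @param max_voxels cap for dense eigendecomposition (default 5000).
#' @param seed seed for the subsample draw when the cap binds.
#' @return object of class `spatial_basis`: list with `vectors`, `values`
#'   (descending), the proximity matrix `W`, `coords`, and `subsample`
#'   (indices into the input, or NULL when no cap was applied).
#' @export
build_spatial_basis <- function(coords, max_voxels = 5000, seed = 1) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 voxel coordinates")
  subsample <- NULL
  if (nrow(coords) > max_voxels) {
    set.seed(seed)
    subsample <- sort(sample.int(nrow(coords), max_voxels))
    coords <- coords[subsample, , drop = FALSE]
    message("spatial basis restricted to a random subsample of ", max_voxels, " voxels")
  }
  d <- as.matrix(stats::dist(coords))
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0)
    stop("duplicate coordinates at voxel pairs: ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  W <- 1 - (d / max(d))^3
  diag(W) <- 0
  n <- nrow(W)
  Wc <- W - matrix(rowMeans(W), n, n) - matrix(colMeans(W), n, n, byrow = TRUE) + mean(W)
  eg <- eigen(Wc, symmetric = TRUE)
  structure(list(vectors = eg$vectors, values = eg$values, W = W,
                 coords = coords, subsample = subsample),
            class = "spatial_basis")
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / sum(W)) * (x'Wx) / (x'x)` with `x` the centered values. Under
#' spatial randomness its expectation is `-1/(n-1)`.
#'
#' @param values numeric vector aligned with the basis voxels.
#' @param basis a `spatial_basis` (or a raw proximity matrix).
#' @return the statistic (numeric scalar).
#' @export
morans_i <- function(values, basis) {
  W <- if (inherits(basis, "spatial_basis")) basis$W else basis
  if (length(values) != nrow(W)) stop("values not aligned with the basis voxels")
  x <- values - mean(values)
  ss <- sum(x^2)
  if (ss == 0) stop("Moran's I undefined for constant values")
  (length(x) / sum(W)) * drop(crossprod(x, W %*% x)) / ss
}

# surrogate maps by the singleton scheme: independent +/-1 flips of the
# spectral coefficients, preserving the spectral power profile (hence the
# map's variance and Moran's I exactly)
msr_surrogates <- function(values, basis, n_surr, seed) {
  x <- values - mean(values)
  co <- drop(crossprod(basis$vectors, x))
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), length(co) * n_surr, replace = TRUE), length(co))
  basis$vectors %*% (co * S) + mean(values)
}

#' Spatially-aware correlation test via Moran spectral randomization
#'
#' Tests the correlation of two voxel maps against a null that preserves the
#' first map's spatial autocorrelation: surrogates of `map_x` are generated
#' by randomizing its coordinates in the Moran eigenvector basis under the
#' "singleton" scheme (independent sign flips of the spectral coefficients),
#' which preserves the spectral power profile, variance and Moran's I of the
#' map. The p-value is `(1 + #{|r_null| >= |r_obs|}) / (1 + n_perm)`
#' (two-tailed; `alternative` gives one-tailed variants).
#'
#' @param map_x,map_y numeric maps on the basis's voxel set.
#' @param basis a `spatial_basis` built from the maps' coordinates.
#' @param n_perm number of surrogates (default 10000; minimum 99).
#' @param seed integer seed.
#' @param procedure surrogate scheme; only `"singleton"` is implemented.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return list with `r_obs`, `p`, `r_null` (the null sample), `n_perm`.
#' @export
msr_correlation_test <- function(map_x, map_y, basis, n_perm = 10000, seed = 1,
                                 procedure = "singleton",
                                 alternative = "two.sided") {
  procedure <- match.arg(procedure, "singleton")
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (stats::sd(map_x) == 0 || stats::sd(map_y) == 0)
    stop("constant map: correlation undefined")
  if (length(map_x) != nrow(basis$vectors) || length(map_y) != length(map_x))
    stop("maps not aligned with the basis voxel set")
  r_obs <- stats::cor(map_x, map_y)
  surr <- msr_surrogates(map_x, basis, n_perm, seed)
  y <- map_y - mean(map_y)
  sc <- surr - matrix(colMeans(surr), nrow(surr), ncol(surr), byrow = TRUE)
  r_null <- drop(crossprod(sc, y)) / (sqrt(colSums(sc^2)) * sqrt(sum(y^2)))
  p <- switch(alternative,
    two.sided = (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + n_perm),
    greater = (1 + sum(r_null >= r_obs)) / (1 + n_perm),
    less = (1 + sum(r_null <= r_obs)) / (1 + n_perm),
    stop("unknown alternative"))
  list(r_obs = r_obs, p = p, r_null = r_null, n_perm = n_perm,
       alternative = alternative)
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6 or 26")
  off
}

#' Watershed partition of a 3-D statistic map
#'
#' Floods the map from its local minima: masked voxels are processed in
#' ascending value order; a voxel with no labelled neighbour starts a new
#' catchment basin (it is a local minimum, with plateau minima merging into
#' the basin opened by their first-processed voxel), a voxel with labelled
#' neighbours joins their basin, and ridge voxels touching several basins
#' are assigned to the neighbouring basin with the deepest minimum (ties to
#' the earlier label).
#'
#' @param stat_map 3-D numeric array.
#' @param mask logical array of the same shape; voxels outside get label 0.
#' @param connectivity 26 (default) or 6.
#' @return integer array of cluster labels, contiguous from 1.
#' @export
watershed_partition <- function(stat_map, mask, connectivity = 26) {
  stopifnot(length(dim(stat_map)) == 3, all(dim(mask) == dim(stat_map)))
  if (!any(mask)) stop("empty mask")
  dm <- dim(stat_map)
  off <- neighbour_offsets(connectivity)
  idx <- which(mask)
  ord <- idx[order(stat_map[idx], idx)]
  labels <- array(0L, dm)
  basin_min <- numeric(0)
  co <- arrayInd(ord, dm)
  for (k in seq_along(ord)) {
    v <- ord[k]
    nb <- sweep(off, 2, co[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] + (nb[ok, 3] - 1L) * dm[1] * dm[2]
    labs <- unique(labels[nb_lin])
    labs <- labs[labs > 0L]
    if (length(labs) == 0L) {
      basin_min <- c(basin_min, stat_map[v])
      labels[v] <- length(basin_min)
    } else if (length(labs) == 1L) {
      labels[v] <- labs
    } else {
      labels[v] <- labs[order(basin_min[labs], labs)][1]
    }
  }
  labels
}
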
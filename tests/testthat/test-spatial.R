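test_that("spatial basis is orthonormal with zero-mean spectrum", {
  set.seed(51)
  coords <- as.matrix(expand.grid(x = 0:5, y = 0:5, z = 0:2)) * 3
  bas <- build_spatial_basis(coords)
  n <- nrow(coords)
  expect_lt(max(abs(crossprod(bas$vectors) - diag(n))), 1e-8)
  expect_true(all(diff(bas$values) <= 1e-10))        # sorted descending
  # trace identity of the doubly centered proximity matrix:
  # mean eigenvalue = -mean(W) (the spectrum is centered on the null level)
  expect_lt(abs(mean(bas$values) + mean(bas$W)), 1e-8)
})

test_that("3-point basis matches a dense eigendecomposition oracle", {
  coords <- cbind(c(0, 1, 2), 0, 0)                  # collinear, equidistant
  bas <- build_spatial_basis(coords)
  d <- as.matrix(dist(coords))
  W <- 1 - (d / max(d))^3; diag(W) <- 0
  H <- diag(3) - matrix(1 / 3, 3, 3)
  eo <- eigen(H %*% W %*% H, symmetric = TRUE)
  expect_equal(bas$values, eo$values, tolerance = 1e-10)
  for (k in 1:3)
    expect_equal(abs(sum(bas$vectors[, k] * eo$vectors[, k])), 1, tolerance = 1e-8)
})

test_that("the basis is invariant to rigid motion of the coordinates", {
  set.seed(52)
  coords <- matrix(runif(30, 0, 20), 10, 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- coords %*% R + matrix(c(5, -3, 11), 10, 3, byrow = TRUE)
  b1 <- build_spatial_basis(coords)
  b2 <- build_spatial_basis(moved)
  expect_equal(b1$W, b2$W, tolerance = 1e-10)
  expect_equal(b1$values, b2$values, tolerance = 1e-10)
  dup <- rbind(coords, coords[1, ])
  expect_error(build_spatial_basis(dup), "duplicate")
})

test_that("Moran's I has its null expectation, eigenvector identity and sign", {
  set.seed(53)
  coords <- as.matrix(expand.grid(x = 0:5, y = 0:5, z = 0:1)) * 3
  bas <- build_spatial_basis(coords)
  n <- nrow(coords)
  # E[I] = -1/(n-1) under spatial randomness
  im <- mean(replicate(2000, morans_i(rnorm(n), bas)))
  expect_equal(im, -1 / (n - 1), tolerance = 0.02)
  # values equal to an eigenvector: I proportional to its eigenvalue
  ks <- which(abs(bas$values) > 0.1)
  ratios <- vapply(c(ks[1], ks[length(ks) %/% 2], ks[length(ks)]), function(k)
    morans_i(bas$vectors[, k], bas) / bas$values[k], 0)
  expect_equal(ratios[1], ratios[2], tolerance = 1e-8)
  expect_equal(ratios[1], ratios[3], tolerance = 1e-8)
  expect_equal(ratios[1], n / sum(bas$W), tolerance = 1e-8)
  # smooth gradient along a line is positively autocorrelated
  line <- cbind(0:19, 0, 0)
  bl <- build_spatial_basis(line)
  expect_gt(morans_i(0:19 + rnorm(20, sd = 0.1), bl), 0)
  expect_error(morans_i(rep(1, n), bas), "constant")
})

test_that("singleton surrogates preserve Moran's I and variance exactly", {
  set.seed(54)
  coords <- as.matrix(expand.grid(x = 0:5, y = 0:5, z = 0:2)) * 3
  bas <- build_spatial_basis(coords)
  x <- drop(bas$vectors %*% (sqrt(pmax(bas$values, 0.05)) * rnorm(nrow(coords))))
  surr <- voxmed:::msr_surrogates(x, bas, 1000, seed = 5)
  i_obs <- morans_i(x, bas)
  i_surr <- apply(surr, 2, morans_i, basis = bas)
  expect_lt(max(abs(i_surr - i_obs)), 5e-10)
  expect_lt(abs(mean(i_surr) / i_obs - 1), 0.05)
  v_surr <- apply(surr, 2, var)
  expect_lt(max(abs(v_surr / var(x) - 1)), 0.01)
})

test_that("msr p-values are invariant to affine rescaling and inputs validated", {
  set.seed(55)
  coords <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:2)) * 3
  bas <- build_spatial_basis(coords)
  n <- nrow(coords)
  x <- drop(bas$vectors %*% (sqrt(pmax(bas$values, 0.05)) * rnorm(n)))
  y <- drop(bas$vectors %*% (sqrt(pmax(bas$values, 0.05)) * rnorm(n)))
  t1 <- msr_correlation_test(x, y, bas, n_perm = 499, seed = 9)
  t2 <- msr_correlation_test(3 * x + 7, -2 * y + 1, bas, n_perm = 499, seed = 9)
  expect_equal(t1$p, t2$p)
  expect_equal(abs(t1$r_obs), abs(t2$r_obs), tolerance = 1e-12)
  expect_error(msr_correlation_test(rep(1, n), y, bas, n_perm = 499), "constant")
  expect_error(msr_correlation_test(x, y, bas, n_perm = 50), "at least 99")
})

test_that("watershed splits the two-well fixture at the ridge", {
  m <- array(c(3, 1, 2, 4, 2, 0, 3), c(7, 1, 1))
  lab <- watershed_partition(m, array(TRUE, dim(m)))
  expect_setequal(unique(as.vector(lab)), 1:2)
  expect_length(unique(lab[1:3]), 1)                 # left basin together
  expect_length(unique(lab[5:7]), 1)                 # right basin together
  expect_false(lab[1] == lab[7])
  # the ridge voxel joins the basin with the deeper minimum (value 0)
  expect_equal(lab[4, 1, 1], lab[6, 1, 1])
})

test_that("watershed yields a partition with one cluster per strict local minimum", {
  set.seed(56)
  m <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  mask <- array(TRUE, dim(m))
  lab <- watershed_partition(m, mask)
  expect_true(all(lab[mask] >= 1))                   # every voxel labeled
  expect_identical(sort(unique(as.vector(lab))), seq_len(max(lab)))
  # count strict local minima under 26-connectivity with an independent loop
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  n_min <- 0
  dm <- dim(m)
  for (v in which(mask)) {
    co <- arrayInd(v, dm)
    nb <- sweep(off, 2, as.vector(co), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (all(m[v] < m[nb[ok, , drop = FALSE]])) n_min <- n_min + 1
  }
  expect_equal(max(lab), n_min)
  # single-minimum map: one cluster covering the mask
  g <- as.matrix(expand.grid(1:5, 1:5, 1:3))
  bowl <- array(rowSums((g - 3)^2), c(5, 5, 3))
  lb <- watershed_partition(bowl, array(TRUE, dim(bowl)))
  expect_identical(sort(unique(as.vector(lb))), 1L)
  expect_error(watershed_partition(bowl, array(FALSE, dim(bowl))), "empty mask")
})

test_that("oversized voxel sets are subsampled with a message", {
  set.seed(57)
  coords <- matrix(runif(3 * 400, 0, 100), 400, 3)
  expect_message(b <- build_spatial_basis(coords, max_voxels = 100), "subsample")
  expect_length(b$subsample, 100)
  expect_equal(nrow(b$vectors), 100)
})
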
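# Synthetic cohorts and voxel stacks with known ground truth.
#
# The generator emulates an adult-lifespan neuroimaging cohort: ages
# near-uniform across the adult range, an IQ-like outcome declining linearly
# with age, and per-voxel demand responses (difficult-minus-easy contrast)
# that decline with age inside an "activated" region. The mediating region's
# voxels share a subject-level latent response, so the mediator -> outcome
# path is real at the voxel level; spatial autocorrelation comes from
# Gaussian smoothing of the voxel noise; bounding-box missingness is
# emulated by per-subject edge slabs.

rerror <- function(n, family) {
  switch(family,
    gaussian = stats::rnorm(n),
    laplace = (stats::rexp(n) - stats::rexp(n)) / sqrt(2),
    uniform = stats::runif(n, -sqrt(3), sqrt(3)),
    `exponential-mixture` = {
      e <- stats::rexp(n) - 1
      s <- ifelse(stats::runif(n) < 0.7, 1, -1)
      e * s
    },
    stop("unknown error_family: ", family)
  )
}

#' Build default effect maps for a simulated grid
#'
#' Places a rectangular "activated, mediating" region in the centre of the
#' grid, covering roughly a tenth of the volume. Inside the region the
#' age slope of the response is `a` (response units per year), the
#' response-to-outcome slope is `b`, and the baseline response is `i1`;
#' outside, all three are zero (no activation, no mediation).
#'
#' @param grid_shape integer vector of voxel counts per axis.
#' @param a,b,d region slope values; `i_in` region baseline.
#' @return list of arrays `a_map`, `b_map`, `d_map`, `i_map`, and the logical
#'   `region` array.
#' @export
default_maps <- function(grid_shape, a = -0.02, b = 7.2, d = 0, i_in = 1.5) {
  stopifnot(length(grid_shape) == 3)
  lo <- pmax(1, floor(grid_shape / 2 - grid_shape / 6) + 1)
  hi <- pmin(grid_shape, ceiling(grid_shape / 2 + grid_shape / 6))
  region <- array(FALSE, grid_shape)
  region[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  mk <- function(v) { m <- array(0, grid_shape); m[region] <- v; m }
  list(a_map = mk(a), b_map = mk(b), d_map = mk(d), i_map = mk(i_in),
       region = region)
}

#' Simulation configuration
#'
#' Collects every ground-truth parameter of the synthetic world. Defaults
#' describe the cohort the pipeline is aimed at: 252 adults aged 20.5-90.3,
#' an IQ-like outcome with total age slope -0.72 points/year (7.2 points per
#' decade) of which 20% is mediated (a*b = -0.144, c' = -0.576), a central
#' activated region whose response declines by 0.02 units/year, 8 mm FWHM
#' spatial smoothing on 3 mm voxels, Laplace structural errors (so causal
#' direction is identifiable), and a per-voxel availability floor of 100
#' subjects.
#'
#' @param n_subjects cohort size.
#' @param age_range low/high age in years; ages drawn uniformly.
#' @param grid_shape voxel counts per axis (3-vector).
#' @param voxel_size mm per axis.
#' @param smooth_fwhm mm FWHM of the spatial noise kernel (0 = unsmoothed).
#' @param a_map,b_map,d_map,i_map per-voxel true slopes / baseline; scalars
#'   are placed in the default central region via [default_maps()].
#' @param c_prime true direct age -> outcome slope.
#' @param noise_sd_mediator SD of the subject-level latent mediator error (e3).
#' @param noise_sd_outcome SD of the outcome error (e2).
#' @param noise_sd_voxel marginal SD of the smoothed per-voxel noise.
#' @param outcome_mean population mean of the outcome at the mean age.
#' @param error_family one of "gaussian", "laplace", "uniform",
#'   "exponential-mixture" for the structural errors e2/e3. Gaussian errors
#'   make causal direction non-identifiable and are recorded for exactly
#'   that purpose.
#' @param moderator_spec list of `list(name=, path=, slope=)` entries; each
#'   adds a standard-normal moderator column whose value shifts the named
#'   path slope by `slope` per SD.
#' @param confounder_spec optional `c(r_UM=, r_UY=)` targets used by
#'   [inject_confounder()].
#' @param missing_floor minimum per-voxel available N for a voxel to be kept.
#' @param missing_prob probability a subject loses one bounding-box face slab.
#' @param slab_geom_prob geometric parameter for slab depth (depth = 1 +
#'   geometric draws).
#' @param seed integer seed.
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(n_subjects = 252, age_range = c(20.5, 90.3),
                       grid_shape = c(12, 12, 8), voxel_size = c(3, 3, 3),
                       smooth_fwhm = 8,
                       a_map = NULL, b_map = NULL, d_map = NULL, i_map = NULL,
                       c_prime = -0.576,
                       noise_sd_mediator = 0.5, noise_sd_outcome = 14.2,
                       noise_sd_voxel = 0.3, outcome_mean = 106.6,
                       error_family = "laplace",
                       moderator_spec = list(), confounder_spec = NULL,
                       missing_floor = 100, missing_prob = 0.5,
                       slab_geom_prob = 0.6, seed = 1) {
  if (n_subjects < 4) stop("configuration error: n_subjects must be >= 4")
  if (length(age_range) != 2 || diff(age_range) <= 0)
    stop("configuration error: invalid age_range")
  if (missing_floor > n_subjects)
    stop("configuration error: missing_floor exceeds n_subjects")
  if (smooth_fwhm < 0) stop("configuration error: smooth_fwhm must be >= 0")
  if (noise_sd_mediator <= 0 || noise_sd_outcome <= 0 || noise_sd_voxel <= 0)
    stop("configuration error: noise SDs must be > 0")
  grid_shape <- as.integer(grid_shape)
  defaults <- default_maps(grid_shape)
  as_map <- function(m, def) {
    if (is.null(m)) return(def)
    if (length(m) == 1) { out <- defaults$a_map; out[] <- 0; out[defaults$region] <- m; return(out) }
    stopifnot(all(dim(m) == grid_shape)); m
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    grid_shape = grid_shape, voxel_size = voxel_size,
    smooth_fwhm = smooth_fwhm,
    a_map = as_map(a_map, defaults$a_map), b_map = as_map(b_map, defaults$b_map),
    d_map = as_map(d_map, defaults$d_map), i_map = as_map(i_map, defaults$i_map),
    c_prime = c_prime, noise_sd_mediator = noise_sd_mediator,
    noise_sd_outcome = noise_sd_outcome, noise_sd_voxel = noise_sd_voxel,
    outcome_mean = outcome_mean, error_family = error_family,
    moderator_spec = moderator_spec, confounder_spec = confounder_spec,
    missing_floor = as.integer(missing_floor), missing_prob = missing_prob,
    slab_geom_prob = slab_geom_prob, seed = as.integer(seed)
  )
  cfg$region <- cfg$b_map != 0
  # latent-mediator ground truth: summary slopes over the mediating region
  cfg$a_bar <- if (any(cfg$region)) mean(cfg$a_map[cfg$region]) else mean(cfg$a_map)
  cfg$b_bar <- if (any(cfg$region)) mean(cfg$b_map[cfg$region]) else 0
  cfg$d_bar <- if (any(cfg$region)) mean(cfg$d_map[cfg$region]) else 0
  cfg$i_bar <- if (any(cfg$region)) mean(cfg$i_map[cfg$region]) else mean(cfg$i_map)
  rerror(1, error_family)  # validate family early
  class(cfg) <- "sim_config"
  cfg
}

mod_slopes <- function(config, path, Z) {
  # summed moderator shift for one path, given standardized moderator matrix
  shift <- 0
  for (m in config$moderator_spec)
    if (m$path == path) shift <- shift + m$slope * Z[, m$name]
  shift
}

#' Generate a synthetic cohort table
#'
#' Draws ages uniformly over the configured range, builds a subject-level
#' latent mediator `M = i_bar + a(Z) * A + e3`, and generates the outcome
#' per the second (plus optional interaction) equation:
#' `C = i2 + b(Z) * M + c'(Z) * A + d * (A - mean A)(M - mean M) + e2`,
#' where each path slope may be shifted linearly by standardized moderators.
#' Head-motion summaries (mean framewise displacement and proportion of
#' high-motion frames) are generated to increase with age.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `cohort_table` with columns `subject_id`,
#'   `A` (age, years), `C` (outcome), one column per moderator,
#'   `motion_mean_fd` (mm) and `motion_prop_high`. The subject-level latent
#'   mediator and structural errors are attached as attributes `latent`
#'   (list with `M`, `e3`) and the full ground truth as `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  A <- stats::runif(n, config$age_range[1], config$age_range[2])
  nz <- length(config$moderator_spec)
  Z <- matrix(numeric(0), n, 0)
  if (nz > 0) {
    nm <- vapply(config$moderator_spec, `[[`, "", "name")
    Z <- matrix(stats::rnorm(n * nz), n, nz, dimnames = list(NULL, nm))
    Z <- scale(Z)  # exact mean 0, SD 1 before path modification
    attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  }
  a_i <- config$a_bar + mod_slopes(config, "a", Z)
  b_i <- config$b_bar + mod_slopes(config, "b", Z)
  cp_i <- config$c_prime + mod_slopes(config, "c_prime", Z)
  e3 <- rerror(n, config$error_family) * config$noise_sd_mediator
  M <- config$i_bar + a_i * A + e3
  e2 <- rerror(n, config$error_family) * config$noise_sd_outcome
  Abar <- mean(config$age_range)
  Mbar <- config$i_bar + config$a_bar * Abar
  i2 <- config$outcome_mean - config$b_bar * Mbar - config$c_prime * Abar
  C <- i2 + b_i * M + cp_i * A + config$d_bar * (A - Abar) * (M - Mbar) + e2
  fd <- pmax(0.03, 0.15 + 0.003 * (A - 20) + stats::rnorm(n, sd = 0.08))
  prop_hi <- pmin(1, pmax(0, 0.02 + 0.35 * (fd - 0.15) + stats::rnorm(n, sd = 0.015)))
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)), A = A, C = C,
                    stringsAsFactors = FALSE)
  if (nz > 0) out <- cbind(out, as.data.frame(Z))
  out$motion_mean_fd <- fd
  out$motion_prop_high <- prop_hi
  attr(out, "latent") <- list(M = M, e3 = e3, a_i = a_i, b_i = b_i)
  attr(out, "truth") <- list(a_bar = config$a_bar, b_bar = config$b_bar,
                             c_prime = config$c_prime, d_bar = config$d_bar,
                             ab = config$a_bar * config$b_bar,
                             c_total = config$a_bar * config$b_bar + config$c_prime)
  class(out) <- c("cohort_table", "data.frame")
  out
}

# Per-axis smoothing matrix for a truncated Gaussian kernel (sigma in voxels)
smooth_matrix <- function(nvox, sigma) {
  if (sigma <= 0) return(diag(nvox))
  half <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-half:half, sd = sigma)
  w <- w / sum(w)
  S <- matrix(0, nvox, nvox)
  for (i in seq_len(nvox)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= nvox
    S[i, j[ok]] <- w[ok]
  }
  S
}

# Smooth an (nx, ny, nz, nsubj) array separably and renormalize so the
# marginal SD is exactly 1 at every voxel (white-noise input assumed).
smooth_noise <- function(noise, grid_shape, voxel_size, fwhm) {
  sigma_vox <- (fwhm / 2.354820045) / voxel_size
  Sx <- smooth_matrix(grid_shape[1], sigma_vox[1])
  Sy <- smooth_matrix(grid_shape[2], sigma_vox[2])
  Sz <- smooth_matrix(grid_shape[3], sigma_vox[3])
  d <- dim(noise)
  x <- matrix(noise, d[1])                       # collapse trailing dims
  x <- Sx %*% x
  x <- array(x, d); x <- aperm(x, c(2, 1, 3, 4))
  x <- Sy %*% matrix(x, d[2]); x <- array(x, d[c(2, 1, 3, 4)])
  x <- aperm(x, c(3, 2, 1, 4))                   # now (z, x, y, s)
  x <- Sz %*% matrix(x, d[3]); x <- array(x, d[c(3, 1, 2, 4)])
  x <- aperm(x, c(2, 3, 1, 4))
  vfac <- outer(outer(rowSums(Sx^2), rowSums(Sy^2)), rowSums(Sz^2))
  sweep(x, 1:3, sqrt(vfac), "/")
}

#' Generate a voxel stack for a cohort
#'
#' Per-voxel values are `i_map + a_map * A + L + noise`, where `L` is the
#' subject's latent mediator deviation (shared by every voxel of the
#' mediating region, zero elsewhere) and the noise is Gaussian white noise
#' smoothed with a separable Gaussian kernel of `smooth_fwhm` mm FWHM and
#' renormalized so `noise_sd_voxel` is the marginal SD. Smoothing is applied
#' before masking. Missingness mimics acquisition bounding-box truncation:
#' with probability `missing_prob` a subject loses a slab of geometric depth
#' from one random face of the volume. Voxels available for fewer than
#' `missing_floor` subjects are dropped.
#'
#' @param config the [sim_config()] used for the cohort.
#' @param cohort the matching [generate_cohort()] output.
#' @return object of class `voxel_stack`: list with `values` (subjects x
#'   voxels, NA where missing), `mask` (logical, same shape), `coords`
#'   (voxels x 3, world mm), `grid_index` (voxels x 3, 0-based), `dim`,
#'   `affine` (4 x 4), `region` (logical, true mediating voxels among those
#'   retained), and `subject_id`.
#' @export
generate_voxel_stack <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"), inherits(cohort, "cohort_table"))
  gs <- config$grid_shape
  sigma_vox <- (config$smooth_fwhm / 2.354820045) / config$voxel_size
  if (any(sigma_vox > gs / 2))
    stop("configuration error: grid too small for the smoothing kernel")
  set.seed(config$seed + 1L)
  n <- nrow(cohort)
  V <- prod(gs)
  lat <- attr(cohort, "latent")
  if (is.null(lat)) stop("cohort lacks latent attributes; not from generate_cohort?")
  L <- lat$M - config$i_bar - config$a_bar * cohort$A   # latent deviation
  noise <- array(stats::rnorm(V * n), c(gs, n))
  if (config$smooth_fwhm > 0)
    noise <- smooth_noise(noise, gs, config$voxel_size, config$smooth_fwhm)
  noise <- matrix(noise, V, n) * config$noise_sd_voxel   # voxels x subjects
  vals <- matrix(config$i_map, V, n) + outer(as.vector(config$a_map), cohort$A) +
    outer(as.vector(config$region), L) + noise
  vals <- t(vals)                                        # subjects x voxels

  # bounding-box missingness: one face slab per affected subject
  mask <- matrix(TRUE, n, V)
  gi <- as.matrix(expand.grid(x = 0:(gs[1] - 1), y = 0:(gs[2] - 1), z = 0:(gs[3] - 1)))
  affected <- stats::runif(n) < config$missing_prob
  faces <- sample(6L, n, replace = TRUE)
  depths <- 1L + stats::rgeom(n, config$slab_geom_prob)
  for (i in which(affected)) {
    ax <- (faces[i] - 1L) %/% 2L + 1L        # axis 1..3
    hi <- faces[i] %% 2L == 0L               # high face?
    dpt <- min(depths[i], gs[ax] %/% 2L)
    idx <- gi[, ax]
    cut <- if (hi) idx >= gs[ax] - dpt else idx < dpt
    mask[i, cut] <- FALSE
  }
  vals[!mask] <- NA_real_
  keep <- colSums(mask) >= config$missing_floor
  affine <- diag(c(config$voxel_size, 1))
  structure(list(
    values = vals[, keep, drop = FALSE], mask = mask[, keep, drop = FALSE],
    coords = gi[keep, , drop = FALSE] %*% diag(config$voxel_size),
    grid_index = gi[keep, , drop = FALSE], dim = gs, affine = affine,
    keep = keep, region = as.vector(config$region)[keep],
    subject_id = cohort$subject_id), class = "voxel_stack")
}

#' Inject a latent confounder of the mediator-outcome relation
#'
#' Adds a latent variable `U` to the summary mediator (every mediating-region
#' voxel is shifted by the same subject offset) and to the outcome such that
#' the realized age-partialled sample correlations of `U` with the mediator
#' and outcome equal `r_UM` and `r_UY` exactly, while the partial
#' mediator-outcome correlation beyond `U` retains its pre-existing value.
#' Infeasible requests - where the target pair cannot coexist with the
#' observed mediator-outcome correlation in a positive-definite correlation
#' matrix - raise an error.
#'
#' @param cohort a `cohort_table`.
#' @param stack the matching `voxel_stack`.
#' @param r_UM,r_UY target correlations (|r| < 1).
#' @param seed integer seed for drawing `U`.
#' @return list with modified `cohort`, `stack`, and the confounder values `U`.
#' @export
inject_confounder <- function(cohort, stack, r_UM, r_UY, seed = 1) {
  if (abs(r_UM) >= 1 || abs(r_UY) >= 1) stop("|r_UM| and |r_UY| must be < 1")
  M <- summary_series(stack, which(stack$region))
  if (anyNA(M)) stop("confounder injection requires complete region data")
  A <- cohort$A; C <- cohort$C
  m_r <- stats::residuals(stats::lm(M ~ A))
  c_r <- stats::residuals(stats::lm(C ~ A))
  rho <- stats::cor(m_r, c_r)
  det3 <- 1 + 2 * r_UM * r_UY * rho - r_UM^2 - r_UY^2 - rho^2
  if (det3 <= 0)
    stop(sprintf(paste0("infeasible confounder: targets (%.2f, %.2f) are ",
                        "incompatible with the observed mediator-outcome ",
                        "correlation %.2f (correlation matrix not positive ",
                        "definite)"), r_UM, r_UY, rho))
  if (r_UM == 0 && r_UY == 0) {
    set.seed(seed)
    return(list(cohort = cohort, stack = stack, U = stats::rnorm(nrow(cohort))))
  }
  set.seed(seed)
  std <- function(x) (x - mean(x)) / stats::sd(x)
  m_s <- std(m_r); c_s <- std(c_r)
  U0 <- stats::rnorm(nrow(cohort))
  U <- std(stats::residuals(stats::lm(U0 ~ A + m_s + c_s)))  # exact orthogonality
  m_new <- r_UM * U + sqrt(1 - r_UM^2) * m_s
  c_new <- r_UY * U + sqrt(1 - r_UY^2) * c_s
  dM <- (m_new - m_s) * stats::sd(m_r)
  dC <- (c_new - c_s) * stats::sd(c_r)
  cohort$C <- C + dC
  reg <- which(stack$region)
  stack$values[, reg] <- stack$values[, reg] + dM
  lat <- attr(cohort, "latent")
  if (!is.null(lat)) { lat$M <- lat$M + dM; attr(cohort, "latent") <- lat }
  list(cohort = cohort, stack = stack, U = U)
}

# mean over selected voxels per subject, NA-aware (internal; exported
# wrappers live in voxelwise.R)
summary_series <- function(stack, voxels) {
  if (length(voxels) == 0) stop("empty voxel set")
  rowMeans(stack$values[, voxels, drop = FALSE], na.rm = TRUE)
}

#' Write / read a cohort table as tab-delimited text
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @return `read_cohort` returns a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(out$subject_id)) stop("duplicate subject_id in cohort table")
  if (anyNA(out$A) || anyNA(out$C)) stop("missing A or C in cohort table")
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a voxel stack as plain text (values TSV + header)
#'
#' The stack is stored as a tab-delimited subjects-by-voxels value matrix
#' (NA for missing) plus a `.hdr.tsv` sidecar holding grid shape, voxel
#' size and per-voxel grid indices, so the volume can be reassembled.
#' @param stack a `voxel_stack`.
#' @param path base path; `path` and `paste0(path, ".hdr.tsv")` are written.
#' @export
write_voxel_stack <- function(stack, path) {
  utils::write.table(cbind(subject_id = stack$subject_id, as.data.frame(stack$values)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  hdr <- data.frame(stack$grid_index,
                    region = as.integer(stack$region))
  names(hdr)[1:3] <- c("ix", "iy", "iz")
  attrline <- sprintf("# dim=%s voxel=%s", paste(stack$dim, collapse = ","),
                      paste(diag(stack$affine)[1:3], collapse = ","))
  con <- file(paste0(path, ".hdr.tsv"), "w")
  writeLines(attrline, con)
  utils::write.table(hdr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
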
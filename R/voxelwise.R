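# Voxel-wise mediation with the hierarchical selection procedure:
# a-path FDR mask -> moderation-screen exclusion -> conjunction FDR.

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`; missing p-values are excluded and
#' returned as NA in both outputs.
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs allowed).
#' @param q FDR level (default 0.05).
#' @return list with logical `reject` and numeric `p_adj` (monotone
#'   non-decreasing in raw-p rank), both aligned with the input.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0)
    return(list(reject = logical(0), p_adj = numeric(0)))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must lie in [0, 1]")
  p_adj <- rep(NA_real_, length(pvalues))
  p_adj[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  reject <- p_adj < q
  reject[!ok] <- NA
  list(reject = reject, p_adj = p_adj)
}

check_alignment <- function(cohort, stack) {
  if (nrow(cohort) != nrow(stack$values) ||
      !identical(as.character(cohort$subject_id), as.character(stack$subject_id)))
    stop("alignment error: cohort and stack subjects differ")
}

#' Voxel-wise mediation with hierarchical selection
#'
#' Fits the mediation system at every voxel with at least `floor` available
#' subjects (each voxel uses only its own available subjects), then selects
#' voxels in three stages: (1) FDR at level `q` on the two-tailed a-path
#' p-values across all floor-passing voxels; (2) exclusion of voxels failing
#' the moderation screen (interaction f^2 >= `f2_max` or p <= `p_min`);
#' (3) FDR at level `q` on the conjunction p-values within the remaining
#' analysis mask. A one-sample group contrast (mean / SD, Cohen's d) is
#' computed per voxel over its available subjects. The summary mask further
#' requires full-sample availability and a positive group contrast.
#'
#' @param cohort a `cohort_table`.
#' @param stack an aligned `voxel_stack`.
#' @param q FDR level for both stages (default 0.05).
#' @param floor minimum per-voxel available N (default 100).
#' @param f2_max,p_min moderation-screen thresholds (defaults 0.02, 0.05).
#' @return object of class `voxel_result_maps`: list with a per-voxel
#'   data.frame `table` (slopes, p-values, f^2, available N, contrast and
#'   its Cohen's d), logical masks `analysis_mask`, `mediation_mask`,
#'   `summary_mask` (NA-free, FALSE where a voxel was below floor), the
#'   adjusted p-value maps, `coords`, and the thresholds used.
#' @export
run_voxelwise <- function(cohort, stack, q = 0.05, floor = 100,
                          f2_max = 0.02, p_min = 0.05) {
  check_alignment(cohort, stack)
  V <- ncol(stack$values)
  n <- nrow(cohort)
  if (floor > n) stop("floor exceeds the cohort size")
  navail <- colSums(stack$mask)
  eligible <- navail >= floor
  if (!any(eligible)) stop("empty result: no voxel passes the availability floor")

  cols <- c("a", "p_a", "b", "p_b_directional", "p_joint", "ab", "f2", "p_d",
            "contrast_mean", "contrast_d", "contrast_p")
  tab <- as.data.frame(matrix(NA_real_, V, length(cols), dimnames = list(NULL, cols)))
  screen_pass <- rep(NA, V)
  for (v in which(eligible)) {
    ok <- stack$mask[, v]
    B <- stack$values[ok, v]
    fit <- fit_mediation(cohort$A[ok], B, cohort$C[ok])
    scr <- moderation_screen(fit, f2_max, p_min)
    m <- mean(B); s <- stats::sd(B)
    tt <- m / (s / sqrt(length(B)))
    tab[v, ] <- c(fit$a, fit$p_a, fit$b, fit$p_b_directional, fit$p_joint,
                  fit$ab, fit$f2_interaction, fit$p_d, m, m / s,
                  2 * stats::pt(abs(tt), length(B) - 1, lower.tail = FALSE))
    screen_pass[v] <- scr$pass
  }
  tab$n_available <- navail

  stage1 <- fdr_bh(ifelse(eligible, tab$p_a, NA), q)
  a_sig <- !is.na(stage1$reject) & stage1$reject
  analysis_mask <- a_sig & !is.na(screen_pass) & screen_pass
  p_conj <- ifelse(analysis_mask, tab$p_joint, NA)
  stage2 <- fdr_bh(p_conj, q)
  mediation_mask <- !is.na(stage2$reject) & stage2$reject
  summary_mask <- mediation_mask & navail == n &
    !is.na(tab$contrast_mean) & tab$contrast_mean > 0
  structure(list(table = tab, analysis_mask = analysis_mask,
                 mediation_mask = mediation_mask, summary_mask = summary_mask,
                 p_a_adj = stage1$p_adj, p_joint_adj = stage2$p_adj,
                 eligible = eligible, coords = stack$coords,
                 q = q, floor = floor, f2_max = f2_max, p_min = p_min),
            class = "voxel_result_maps")
}

#' Summarize a voxel stack within regions of interest
#'
#' The response within each ROI is the per-subject mean across the ROI's
#' available voxels; subjects with no available in-ROI voxel get NA.
#'
#' @param stack a `voxel_stack`.
#' @param roi_masks named list; each element is either a logical/0-1 3-D
#'   array on the stack's grid or a logical/integer index over the stack's
#'   retained voxels.
#' @return data.frame of per-subject ROI means, one column per ROI.
#' @export
roi_summarize <- function(stack, roi_masks) {
  stopifnot(is.list(roi_masks), !is.null(names(roi_masks)))
  out <- lapply(names(roi_masks), function(nm) {
    m <- roi_masks[[nm]]
    if (is.array(m) && length(dim(m)) == 3) {
      if (!all(dim(m) == stack$dim)) stop("ROI ", nm, " is not on the stack's grid")
      sel <- as.vector(m != 0)[stack$keep]
    } else if (is.logical(m)) sel <- m else sel <- seq_len(ncol(stack$values)) %in% m
    if (!any(sel)) stop("ROI ", nm, " is empty")
    vals <- stack$values[, sel, drop = FALSE]
    s <- rowMeans(vals, na.rm = TRUE)
    s[rowSums(!is.na(vals)) == 0] <- NA
    s
  })
  names(out) <- names(roi_masks)
  as.data.frame(out)
}

#' Per-ROI mediation table
#'
#' One row per ROI: the group contrast (Cohen's d, p, FDR-adjusted p), the
#' age-by-response moderation screen (interaction Cohen's d, p, adjusted p)
#' and the mediation result (indirect effect `ab`, conjunction p, adjusted
#' p). FDR adjustment is across ROIs, per column family.
#'
#' @param cohort a `cohort_table`.
#' @param stack an aligned `voxel_stack`.
#' @param roi_masks as in [roi_summarize()].
#' @return a data.frame, one row per ROI.
#' @export
roi_mediation_table <- function(cohort, stack, roi_masks) {
  check_alignment(cohort, stack)
  series <- roi_summarize(stack, roi_masks)
  rows <- lapply(names(series), function(nm) {
    ok <- !is.na(series[[nm]])
    B <- series[[nm]][ok]
    fit <- fit_mediation(cohort$A[ok], B, cohort$C[ok])
    m <- mean(B); s <- stats::sd(B); nn <- length(B)
    tt <- m / (s / sqrt(nn))
    data.frame(roi = nm, n = nn, contrast_d = m / s,
               contrast_p = 2 * stats::pt(abs(tt), nn - 1, lower.tail = FALSE),
               mod_d = 2 * fit$d / fit$se_d / sqrt(fit$n - 4),
               mod_p = fit$p_d, ab = fit$ab, p_joint = fit$p_joint,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$contrast_p_adj <- fdr_bh(tab$contrast_p)$p_adj
  tab$mod_p_adj <- fdr_bh(tab$mod_p)$p_adj
  tab$p_joint_adj <- fdr_bh(tab$p_joint)$p_adj
  tab[, c("roi", "n", "contrast_d", "contrast_p", "contrast_p_adj",
          "mod_d", "mod_p", "mod_p_adj", "ab", "p_joint", "p_joint_adj")]
}

#' Summary mediator series over the selected voxels
#'
#' Per-subject mean of the stack over the summary mask (voxels with
#' significant mediation, full-sample data and a positive group contrast).
#'
#' @param maps a `voxel_result_maps` from [run_voxelwise()].
#' @param stack the same `voxel_stack`.
#' @return numeric per-subject series.
#' @export
summary_mediator <- function(maps, stack) {
  sel <- which(maps$summary_mask)
  if (length(sel) == 0)
    stop("empty summary mask: no voxel satisfies mediation + full N + positive contrast")
  summary_series(stack, sel)
}
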
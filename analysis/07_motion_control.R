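#!/usr/bin/env Rscript
# Step 7: model diagnostics and the head-motion control analysis. RESET
# checks the functional form and the White/Wooldridge test the residual
# variance of each mediation equation; then every key variable (age,
# outcome, moderators, and each voxel) is residualized on the framewise-
# displacement summaries and the voxel-wise analysis repeated.

source(file.path("analysis", "00_config.R"))
d <- study_data()
out <- results_dir()

vw <- run_voxelwise(d$cohort, d$stack, q = 0.05, floor = 100)
Msum <- summary_series_robust(vw, d$stack)
fit <- fit_mediation(d$cohort$A, Msum, d$cohort$C)

dg <- diagnostic_report(fit, d$cohort$A, Msum, d$cohort$C)
rows <- do.call(rbind, lapply(names(dg), function(eq) data.frame(
  equation = eq,
  reset_F = dg[[eq]]$reset$statistic, reset_df2 = dg[[eq]]$reset$df[2],
  reset_p = dg[[eq]]$reset$p,
  white_chi2 = dg[[eq]]$white$statistic, white_p = dg[[eq]]$white$p)))
print(cbind(rows[1], round(rows[-1], 4)), row.names = FALSE)

cat(sprintf("motion summaries: mean FD %.3f mm (r with age %.2f), prop high %.3f\n",
            mean(d$cohort$motion_mean_fd),
            cor(d$cohort$A, d$cohort$motion_mean_fd),
            mean(d$cohort$motion_prop_high)))

res <- residualize_all(d$cohort, d$stack)
vw_m <- run_voxelwise(res$cohort, res$stack, q = 0.05, floor = 100)
fit_m <- fit_mediation(res$cohort$A, summary_series_robust(vw_m, res$stack),
                       res$cohort$C)
cat(sprintf("before motion control: mediation mask %d voxels, ab = %.4f (%.1f%% of total)\n",
            sum(vw$mediation_mask), fit$ab, 100 * fit$ab / fit$c))
cat(sprintf("after motion control:  mediation mask %d voxels, ab = %.4f (%.1f%% of total)\n",
            sum(vw_m$mediation_mask), fit_m$ab, 100 * fit_m$ab / fit_m$c))

write.table(rows, file.path(out, "diagnostics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote diagnostics.tsv\n")
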
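#!/usr/bin/env Rscript
# Step 4: LOVE sensitivity analysis of the summary mediation model - how
# strongly would an unmodeled confounder have to correlate with both the
# summary response and the outcome (given age) to reduce the indirect
# effect to zero?

source(file.path("analysis", "00_config.R"))
d <- study_data()
out <- results_dir()

vw <- run_voxelwise(d$cohort, d$stack, q = 0.05, floor = 100)
Msum <- summary_series_robust(vw, d$stack)
fit <- fit_mediation(d$cohort$A, Msum, d$cohort$C)
surf <- love_surface(fit, d$cohort$A, Msum, d$cohort$C)
th <- confounding_threshold(surf)

cat(sprintf("observed ab = %.4f; age-partialled mediator-outcome r = %.3f\n",
            fit$ab, surf$rho))
cat(sprintf("to nullify the mediation, both confounder correlations must average > %.3f\n",
            th$min_average))
cat(sprintf("and at least one must exceed %.3f (diagonal threshold r* = %.3f)\n",
            th$min_single, th$r_star))

grid_tab <- data.frame(r_um = rep(surf$r_um, times = length(surf$r_uy)),
                       r_uy = rep(surf$r_uy, each = length(surf$r_um)),
                       ab_adj = as.vector(surf$ab_adj),
                       feasible = as.vector(surf$feasible))
write.table(round(grid_tab, 6), file.path(out, "love_surface.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote love_surface.tsv\n")
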
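#!/usr/bin/env Rscript
# Step 1: generate the synthetic cohort and voxel stack, and describe the
# three bivariate relationships (age-outcome, age-response, response-outcome)
# that motivate the mediation model.

source(file.path("analysis", "00_config.R"))
d <- study_data()
out <- results_dir()

cat(sprintf("cohort: n = %d, ages %.1f-%.1f years\n",
            nrow(d$cohort), min(d$cohort$A), max(d$cohort$A)))
cat(sprintf("outcome: mean %.1f, SD %.1f\n", mean(d$cohort$C), sd(d$cohort$C)))
cat(sprintf("age-outcome: r = %.3f, slope = %.2f points/decade\n",
            cor(d$cohort$A, d$cohort$C),
            10 * cov(d$cohort$A, d$cohort$C) / var(d$cohort$A)))

nav <- colSums(d$stack$mask)
cat(sprintf("voxels retained: %d (floor %d); %.0f%% with the full sample, %.0f%% with >= 90%%\n",
            ncol(d$stack$values), d$cfg$missing_floor,
            100 * mean(nav == nrow(d$cohort)),
            100 * mean(nav >= 0.9 * nrow(d$cohort))))

M <- roi_summarize(d$stack, list(region = which(d$stack$region)))$region
cat(sprintf("true-region mean response: r(age) = %.3f, r(outcome) = %.3f\n",
            cor(d$cohort$A, M, use = "complete.obs"),
            cor(d$cohort$C, M, use = "complete.obs")))

write_cohort(d$cohort, file.path(out, "cohort.tsv"))
write.table(data.frame(voxel = seq_along(nav), n_available = nav,
                       in_region = d$stack$region),
            file.path(out, "voxel_availability.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", file.path(out, "cohort.tsv"), "and voxel_availability.tsv\n")
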
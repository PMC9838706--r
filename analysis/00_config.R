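# Shared study configuration for the analysis scripts. Each numbered script
# sources this file and regenerates the synthetic cohort deterministically,
# so every step can be run standalone.

library(voxmed)

STUDY_SEED <- 20260918L

study_config <- function(seed = STUDY_SEED) {
  sim_config(
    n_subjects = 252, age_range = c(20.5, 90.3),
    grid_shape = c(12, 12, 8), voxel_size = c(3, 3, 3), smooth_fwhm = 8,
    missing_floor = 100, seed = seed,
    # lifestyle-style moderators: "variety" attenuates the brain->outcome
    # path by 2 outcome units per mediator unit per SD of the moderator
    # (about 0.55*b across 2 SDs); the others are inert
    moderator_spec = list(
      list(name = "variety", path = "b", slope = -2.0),
      list(name = "frequency", path = "b", slope = 0),
      list(name = "duration", path = "b", slope = 0)
    )
  )
}

study_data <- function(seed = STUDY_SEED) {
  cfg <- study_config(seed)
  cohort <- generate_cohort(cfg)
  list(cfg = cfg, cohort = cohort, stack = generate_voxel_stack(cfg, cohort))
}

results_dir <- function() {
  d <- file.path("results", "analysis")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# summary mediator with fallback for desk-scale grids where no mediating
# voxel retains the full sample (see methods vignette)
summary_series_robust <- function(vw, stack) {
  pos <- !is.na(vw$table$contrast_mean) & vw$table$contrast_mean > 0
  for (sel in list(vw$summary_mask, vw$mediation_mask & pos,
                   vw$analysis_mask & pos)) {
    if (any(sel)) return(roi_summarize(stack, list(s = which(sel)))$s)
  }
  stop("no voxel available for the summary mediator")
}
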
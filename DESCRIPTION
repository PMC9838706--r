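Package: voxmed
Title: Voxel-Wise Mediation of Age-Related Differences in Fluid Intelligence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and inference tools for asking whether, and where, a
    per-voxel brain response mediates age-related differences in an IQ-like
    outcome. Implements the four-regression mediation system with
    joint-significance (conjunction) testing and bias-corrected bootstrap
    intervals; hierarchical voxel-wise selection under false-discovery-rate
    control; spatial-autocorrelation-aware map correlation via Moran
    eigenvector spectral randomization; watershed partitioning of statistic
    maps; left-out-variable (LOVE) sensitivity analysis for unmeasured
    mediator-outcome confounding; ICA-LiNGAM causal-direction estimation with
    a cluster bootstrap; Edwards-Lambert moderated mediation; and regression
    diagnostics (RESET, White/Wooldridge) with head-motion controls. A
    synthetic-cohort generator with known ground truth drives every stage, so
    the whole pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
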
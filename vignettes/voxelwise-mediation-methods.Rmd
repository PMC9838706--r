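---
title: "Methods: voxel-wise mediation of age-related cognitive decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise mediation of age-related cognitive decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery in `voxmed`: the models
and their assumptions, the synthetic world the tests run against, the
numerical choices that were genuinely open, and what a green test suite
does and does not establish.

## 1. The mediation system

The pipeline asks whether a brain response `B` (a difficult-minus-easy BOLD
contrast, per voxel or averaged over a region) mediates the dependence of
an IQ-like outcome `C` on age `A`. Four OLS regressions define the system:
the total effect (`C` on `A`), the direct-plus-mediator model (`C` on `B`
and `A`), the age effect on the response (`B` on `A`), and a moderation
screen that adds the product `AB`. The indirect effect is `ab = a*b`, which
for OLS on a common sample equals `c - c'` exactly; the suite asserts this
identity to 1e-10 on every fit and bootstrap resample, which pins down the
whole estimation path.

Assumptions worth stating: linearity of all three relations in the observed
range, homoscedastic residuals (both checked by the diagnostics module),
exogenous age (age can cause but not be caused), and no unmodeled
confounding of the `B`–`C` relation (addressed by the sensitivity module,
not assumed away).

**Conjunction test.** Mediation is declared only when both the `a` and `b`
paths are individually significant, with the conjunction p-value
`max(p_a, p_b)`. This is conservative relative to testing the product
`ab` directly, but controls type-I error under either single null (`a = 0`
or `b = 0`); the acceptance suite verifies this empirically at n = 250 and
2000 replicates. The `b` test is one-tailed for the sign opposite to `a`
("consistent" mediation — the indirect path must act in the same direction
as the total effect); when `a` is exactly zero the two-tailed p is returned
and flagged.

**Centering in the screen.** Whether the `AB` product was formed from raw
or centered variables is not observable from the test statistics — the `d`
coefficient, its t test and its Cohen's f² are invariant — so the package
mean-centers `A` and `B` before forming the product, purely for numerical
conditioning. f² is computed as `(R²_full − R²_reduced)/(1 − R²_full)`
against the no-interaction model, with defaults f² < 0.02 and p > 0.05
(two-tailed, uncorrected) to pass the screen.

**Bias-corrected bootstrap.** Inference for `ab` (and for compound
moderated paths) uses whole-subject case resampling and the BC (no
acceleration) percentile interval: `z0 = qnorm(fraction of resamples below
the point estimate)`, bounds at the `pnorm(2 z0 ∓ z_{0.975})` percentiles
(quantile type 6). Degenerate resamples (constant `A` or `B`) are redrawn
and counted, with a warning above 1% — chosen over NaN propagation for CI
stability at small n. Two-sided p-values for compound paths invert the
interval: `p = 2 min(Φ(ẑ), 1−Φ(ẑ))` with `ẑ = qnorm(P(boot < 0)) − 2 z0`.
The default of 15,000 resamples follows standard practice for BC intervals;
tests use fewer (500–2000) for budget, which the calibration checks show is
already adequate for 95% intervals.

## 2. The synthetic world

The generator's defaults state one cohort, chosen once:

* n = 252 adults, ages uniform on 20.5–90.3 (the lifespan design samples
  roughly equally by decile; uniform is the simple version of that);
* outcome mean 106.6, total age slope −0.72 points/year (7.2 points per
  decade, r(age, outcome) ≈ −0.7), of which 20% is mediated:
  `a = −0.02` response units/year in the activated region, `b = 7.2`
  outcome units per response unit, `c' = −0.576`;
* mediator residual SD 0.5, outcome residual SD 14.2 (these reproduce the
  stated correlation structure), per-voxel smoothed noise SD 0.3;
* a central box covering ~10% of a 12×12×8 grid of 3 mm voxels is both
  activated (baseline 1.5) and mediating; elsewhere `a = b = 0`;
* spatial autocorrelation from an 8 mm FWHM separable Gaussian kernel,
  renormalized so the marginal noise SD is exact at every voxel;
* Laplace structural errors by default, so causal direction is identifiable
  (`error_family = "gaussian"` is accepted and is the documented
  non-identifiable case);
* bounding-box missingness: with probability 0.5 a subject loses a slab of
  geometric depth from one random face, and voxels below 100 available
  subjects are dropped.

**The latent-mediator coupling.** The outcome must depend on the *voxel*
responses for a voxel-level `b` path to exist, yet the cohort is generated
before the stack. The generator resolves this with a subject-level latent
response `M = i + a(Z)·A + e3` that feeds the outcome, and gives every
mediating-region voxel that subject deviation plus voxel-specific smoothed
noise. Consequences worth knowing: per-voxel `b` estimates are attenuated
relative to the configured `b` by the voxel-noise reliability factor, and
region-mean summaries recover `b` only up to that attenuation (≈ 0.7–0.8
at the defaults). Tests that assert exact recovery therefore target the
latent mediator; pipeline tests target detection and ranking, not the raw
coefficient value.

**What the generator does not emulate:** haemodynamics or task structure,
brain geometry (rectangular grids only), realistic voxel counts, spatially
varying smoothness, or the empirical distribution of per-voxel N. On the
last point: with iid random-face slabs and 252 subjects, a desk-scale grid
has almost no voxel untouched by every subject, so the fraction of voxels
with the *full* sample is far smaller than in real acquisitions (where the
grid is much larger relative to the truncated margin). The strict summary
mask (mediation + full N + positive contrast) can therefore be empty at
some seeds; the analysis scripts then fall back to the mediation (or
analysis) mask with positive contrast, using availability-aware means. The
package functions themselves keep the strict definition and raise an
explicit error on an empty mask.

**Confounder injection** rebuilds the age-partialled, standardized mediator
and outcome residuals as exact linear combinations of a Gram–Schmidt-
orthogonalized latent `U`, so the realized partial correlations equal the
targets to machine precision while the mediator–outcome association beyond
`U` is preserved. Requests incompatible with a positive-definite
(U, M, C) correlation matrix — given the observed mediator–outcome
correlation — are rejected.

## 3. Spatial statistics

**Proximity kernel.** The Moran eigenvector basis uses
`W_ij = 1 − (d_ij/d_max)³` (zero diagonal), doubly centered and
eigendecomposed in full. The cubic-decay kernel is a standard choice in the
Moran-eigenvector-map literature; the method's validity is carried by the
calibration simulation, not by the specific kernel, and the proximity
matrix is exposed for substitution. A trace identity worth recording: with
a zero diagonal, the centered matrix has `mean(eigenvalues) = −mean(W)`,
not zero. Dense eigendecomposition caps the voxel set at 5000 (random
subsample, logged).

**Surrogates.** The "singleton" scheme flips the sign of each spectral
coefficient independently. Because that preserves the squared coefficient
profile exactly, every surrogate has *exactly* the source map's variance
and Moran's I — the surrogate contract tests assert this at 5e-10. The
permutation p is `(1 + #{|r_null| ≥ |r_obs|})/(1 + n_perm)`, two-tailed by
default, 10,000 permutations by default.

**Calibration caveat.** Sign-flip surrogates treat the spectral
coefficients as independent and symmetric. That is exact for random fields
generated with independent coefficients in this basis (the acceptance
calibration world), and approximate for Gaussian-kernel-smoothed fields,
whose coefficients in the proximity eigenbasis are correlated: there the
test runs slightly hot (empirically ~0.06–0.09 rejection at nominal 0.05
on a 256-voxel grid). A naive value-permutation test on the same smooth
maps rejects at 10× nominal and is the failure mode the method exists to
avoid.

**Watershed.** Masked voxels are processed in ascending value order: a
voxel with no labelled neighbour opens a basin (exactly the strict local
minima; plateau minima merge into the basin of their first-processed
member), others join their neighbours' basin, and ridge voxels touching
several basins go to the one with the deepest minimum (ties to the earlier
label). Connectivity is 26-neighbour by default with a 6-neighbour option.
Cluster counts depend on grid resolution and smoothness; no specific count
is a target.

## 4. Sensitivity analysis (LOVE)

The confounder correlations `(r_UM, r_UY)` are interpreted as partial
correlations given age (age being exogenous, a confounder cannot bias the
`a` path); a marginal interpretation is available by flag. The adjusted
mediator→outcome path follows omitted-variable algebra:
`b_adj = (ρ − r_UM r_UY)/(1 − r_UM²) · sd(C|A)/sd(M|A)`, with `ρ` the
observed age-partialled `M`–`C` correlation, and `ab_adj = a · b_adj`. This
equals — exactly, at the sample level — the `b` coefficient from refitting
the second equation with a `U` of the stated correlations included, which
is the oracle the tests use. One subtlety the algebra forces: along the
`r_UY = 0` axis the adjusted effect is `ab/(1 − r_UM²)`, *not* `ab`; a
regressor correlated with `M` but not `C` shrinks the residual variance of
`M` and inflates the coefficient. The zero contour lies on
`r_UM r_UY = ρ`; the threshold `r*` is found by sign-change interpolation
along the diagonal matched to `ρ`'s sign, with the "average exceeds" and
"at least one exceeds" summaries taken from the interpolated contour.
Grid points whose implied (U, M, C) correlation matrix is not positive
definite are flagged infeasible and excluded. Default grid: 101 × 101 over
[−0.9, 0.9]².

## 5. Causal direction (ICA-LiNGAM)

Variables are standardized (the estimator is not scale invariant). ICA is
fixed-point negentropy maximization with the tanh contrast and **symmetric
(parallel) decorrelation**, tolerance 1e-8, up to 5 seeded restarts with
the best converged run kept by negentropy. Symmetric decorrelation was
chosen over deflation after direct comparison: deflation's sequential error
accumulation flipped the recovered causal order on a large fraction of
bootstrap resamples at n = 500, while the symmetric update matched a
reference implementation's stability. Non-convergence after all restarts is
an error carrying the seeds tried — expected behaviour for Gaussian data,
where the model is unidentifiable (the acceptance suite documents
near-chance order recovery there).

From the unmixing matrix, rows are permuted to maximize diagonal dominance
(exhaustive up to 6 variables), scaled to unit diagonal, and `B = I − W`.
The causal order is found by zeroing the `m(m+1)/2` smallest-magnitude
entries (entries below 1e-3 are structural zeros first) and searching row
permutations for strict lower-triangularity, zeroing one further entry at a
time if needed; needing extra zeroing raises the `not_triangular` flag.
With three variables and a missing true edge, one spurious small entry
survives pruning about as often as not, so the flag fires frequently on
weakly-identified fits — which is exactly why the cluster bootstrap uses it
as a discard rule. Final connection strengths are re-estimated by OLS of
each variable on its predecessors in the recovered order (the standard
final step), which stabilizes the per-pair directionality scores
(|hypothesized| − |reverse|; the hypothesized edge set is a parameter, with
age → response, age → outcome, response → outcome as the 3-variable
default).

The cluster bootstrap resamples subjects, refits LiNGAM per watershed
cluster (cluster-mean mediator), discards clusters whose *undirected*
coefficient signs — read as the nonzero one of each pair's two directed
coefficients — mismatch the all-voxel reference, or whose fit is flagged
non-triangular, and averages directionality over retained clusters;
resamples retaining no cluster are recorded as missing (warning above
50%). BC intervals are built from the resample means by the shared BC
implementation.

## 6. Moderated mediation

First stage `B ~ A + Z + A:Z`; second stage `C ~ B + A + Z + B:Z + A:Z`,
with `A`, `B` mean-centered before products and `Z` standardized, refitted
from scratch (including restandardization) inside every bootstrap
resample. The second stage includes `A:Z` so moderation of the direct path
is estimable alongside `b` moderation; the `A:B` term is excluded,
consistent with the pipeline's earlier no-moderation-by-age screen.
Simple effects are evaluated at ±1 SD; each Δ is the change across those 2
SDs, so `Δ(ab) = a(+1)b(+1) − a(−1)b(−1)` exactly (asserted on every fit
and resample). Single paths get parametric interaction tests; compound
paths get BC bootstrap p-values. Listwise deletion per moderator reproduces
the varying-N bookkeeping of questionnaire data, and
`residualize_moderators()` implements the residualize-on-the-others
variant. A power note: at the generator's paper-anchored noise level, a
b-path moderation of ~0.55·b across 2 SDs sits near the detection boundary
at n = 252 — single-seed runs can land either side of p = 0.05; the
recovery acceptance test therefore uses a lower outcome noise
(its "strong effects" world) where the estimate, not the verdict, is the
assertion.

## 7. Diagnostics and motion control

RESET augments the design with powers 2–4 of the standardized fitted
values (3 numerator df); White/Wooldridge regresses squared residuals on
fitted values and their squares (`n·R²` on 2 df). Both hold their nominal
size within Monte-Carlo bands at n = 250 in the acceptance suite. The
latent outcome score is the first principal component of the standardized
subtests, sign-fixed to correlate positively with the subtest sum (the PCA
sign being arbitrary) and affinely rescaled. Framewise displacement sums
absolute translation increments plus a 50 mm radius times absolute rotation
increments — the radius is a convention, exposed as an argument, with the
0.9 mm high-motion threshold as default. `residualize_all()` replaces age,
outcome, moderators and every voxel (over its available subjects) by
residuals on the motion covariates; it is idempotent, and the planted-
confounder test shows a motion-driven spurious `ab` collapsing to zero
after control.

## 8. Test-budget scaling

Simulation designs that would be expensive at their stated sizes run
scaled down with thresholds unchanged: the cluster-bootstrap recovery check
uses 10 replicates × 5 clusters × 200 resamples; compound-path bootstrap
calibration uses 500 replicates × 500 resamples; bootstraps in unit tests
use 1000–2000 resamples instead of 15,000. The full suite runs in under
10 minutes on one CPU.

## 9. Known limitations

No haemodynamic forward model or task simulation; rectangular grids only;
the shipped pipeline applies LiNGAM to exactly three variables (the
functions accept more, up to the exhaustive-permutation limit of six); no
robust/sandwich standard errors; no counterfactual (natural direct/
indirect) estimands, multilevel mediation, or multiple simultaneous
mediators; MSR calibration is approximate for kernel-smoothed fields as
described above; and cross-sectional mediation cannot, by design,
establish within-person change — the causal-direction module tests
consistency with a causal ordering, not the ordering itself.
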
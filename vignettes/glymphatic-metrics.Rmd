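---
title: "Multi-compartment glymphatic metrics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-compartment glymphatic metrics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphr)
```

## The bi-tensor signal model

`glymphr` treats each voxel as a two-compartment mixture,

$$S(b, g) = S_0\left[f\,e^{-b\,g^\top D_f g} + (1-f)\,e^{-b\,g^\top D_t g}\right],$$

with a free-water volume fraction $f$ (FWVF), a fluid tensor $D_f$ and a
tissue tensor $D_t$. The assumptions are those of any two-compartment
diffusion model: slow exchange between compartments over the diffusion
time, Gaussian diffusion within each compartment, and a mono-exponential
decay per compartment across the b-values used. The distinctive choice is
that $D_f$ is a *full* tensor rather than the isotropic
$d_{\mathrm{free}} I$ of classical free-water elimination: perivascular
spaces are fluid-filled conduits, so fluid diffusivity along them (the
fluid axial diffusivity, FWAD) carries the physiology of interest, and an
isotropic constraint would erase it. The isotropic model remains available
(`fit_isotropic_fwe()`), both as a baseline and as the warm start of the
anisotropic fit.

Identifiability requires at least two distinct nonzero shells; fitting on
a single shell is refused. The two preset schemes
(`make_scheme("hcpa")`: 6 b0 + 45 directions at b = 1500 + 45 at
b = 3000 s/mm²; `make_scheme("adni")`: 14 b0 + 6 at 500 + 56 at 1000 +
56 at 2000) reproduce the shell layouts of the two public cohorts this
kind of analysis targets. Direction sets are generated by seeded
electrostatic repulsion — the actual scanner tables are not public, and
only the shell structure matters for the estimator's conditioning.

## Estimation

Per voxel, estimation is staged:

1. log-linear single-tensor fit over all shells (closed form);
2. isotropic free-water-elimination fit: a deterministic grid over
   $f \in \{0.02, 0.06, \ldots, 0.98\}$ with a closed-form tissue fit at
   each $f$, refined by Levenberg–Marquardt over
   $(\operatorname{logit} f, \operatorname{chol} D_t)$;
3. the anisotropic fit over 13 parameters — $\operatorname{logit} f$ and
   the Cholesky factors of both tensors, which guarantees positive
   semi-definiteness without explicit constraints — started from stage 2
   with $D_f = 3.0\times10^{-3} I$, plus one deterministic restart at
   $f_0 = 0.8$ (the objective is multi-modal; the restart recovers the
   rare voxel where the staged start lands in the wrong basin).

$S_0$ is fixed at the mean of the b0 volumes rather than fitted: with 6–14
b0 samples its standard error is well below the other sources of error,
and removing it from the optimization avoids a near-degenerate direction.
The objective is ordinary least squares on magnitudes. The
Levenberg–Marquardt Jacobian is analytic (chain rule through the Cholesky
parameterization; eigenvalue-penalty rows via
$\partial\lambda_k/\partial D = v_k v_k^\top$), which makes a voxel fit a
few tens of milliseconds.

### Constraints and the fluid-MD prior

The two compartments are distinguished only by their diffusivity scales,
so unconstrained fits can swap them on noisy data. Three devices prevent
this:

- eigenvalue bounds enforced by penalty: tissue
  $\lambda \in [0.05, 2.5]\times10^{-3}$, fluid
  $\lambda \in [2.0, 6.0]\times10^{-3}$ mm²/s. The fluid floor of
  $2.0\times10^{-3}$ keeps the ranges disjoint; with an overlapping floor
  the fluid compartment absorbs tissue signal at realistic noise levels
  and the free-water fraction inflates by ~0.1. Free water at body
  temperature diffuses at ~$3.0\times10^{-3}$ mm²/s, so the floor stays
  well below any plausible fluid eigenvalue;
- a label-switching convention: the returned fluid tensor is always the
  compartment with the larger mean diffusivity;
- a weak prior pulling fluid MD toward $3.0\times10^{-3}$ (penalty weight
  `md_prior_weight = 1e-3` on the relative deviation). The weight is
  deliberately small: at b = 1500/3000 the free-water signal is attenuated
  to roughly 1%, so the fluid tensor is ill-conditioned and even a
  moderate prior (1e-2) biases noiseless FWAD recovery beyond 5%. At 1e-3
  the prior only matters where the data say nothing.

All tolerances: LM `ftol = ptol = 1e-6`, `gtol = 1e-8`, at most 500
iterations. Non-convergence is flagged on the returned object, never
raised as an error, and if the anisotropic stage fails to improve on its
warm start the warm start is returned (the reported RSS never exceeds the
initialization's).

### Volume-level refinements

`fit_volume()` adds two optional (default-on) refinements that operate on
information a single voxel does not have:

- **Rician floor correction.** Magnitude noise is Rician; at high b the
  floor $\sigma\sqrt{\pi/2}$ masquerades as signal. The noise SD is pooled
  as the median over mask voxels of the SD across repeated b0 volumes, and
  magnitudes are corrected by the method of moments
  ($E[M^2] = S^2 + 2\sigma^2$, i.e.
  $\hat S = \sqrt{\max(M^2 - 2\sigma^2, (0.3\sigma)^2)}$). This is a data
  correction, not a Rician likelihood; it is exactly a no-op on noiseless
  data.
- **Spatial anchor pass.** Per-voxel two-compartment fits have a strong
  $f$/tissue-MD trade-off (correlation ≈ −0.97 at SNR 30 in our
  phantoms). A second pass refits each voxel with soft penalties (weight
  2 per $10^{-3}$ mm²/s) pulling the tissue and fluid mean diffusivities
  toward their 26-neighborhood medians from the first pass — the same
  borrowing of spatial strength that regularized free-water-elimination
  methods use. Anchors are computed from the full first pass, so the
  result is independent of voxel order. On a 1000-voxel SNR-30 phantom
  this cuts the FWVF mean absolute error from ~0.04 to ~0.026.

Both refinements are volume-level; `fit_bitensor()` on one voxel is left
untouched, and a one-voxel mask with the refinements disabled reproduces
the single-voxel fit exactly.

## DTI-ALPS

The index is the ratio of the mean x-diffusivity in the projection- and
association-fiber ROIs to the mean of the diffusivities perpendicular to
both the fibers and the vessels
($D_{yy}$ in the projection ROI, $D_{zz}$ in the association ROI). It is
1 in an isotropic medium and invariant to global scaling. Diffusivities
come from the conventional single-tensor fit by default
(`fit_dti_volume()`), matching the original ALPS formulation; the
tissue-tensor maps of the bi-tensor fit (`tDxx`/`tDyy`/`tDzz`) can be
substituted. ROIs are supplied as voxel sets (`alps_roi()`); automatic
color-FA-guided placement would need template registration and is out of
scope. Whether a study reports unilateral or bilaterally averaged indices
varies; passing a list of ROIs returns the arithmetic mean of the
per-ROI indices, which is our default reading of a "single global
measure".

## Perivascular-space morphometry

Components are labeled by flood fill (26-connectivity default; 6 and 18
available), ordered by volume with ties broken by first voxel index, so
labels are deterministic. The diameter of a component is defined as twice
the mean interior distance-transform value over its medial-axis voxels
(local maxima of the interior distance among 26-neighbors); a single-voxel
component is assigned the smallest voxel spacing and flagged. Elongation
is the principal-axis length over the mean orthogonal width from the
voxel-cloud covariance (≥ 1 by construction).

False-positive exclusion applies, in order: WMH overlap (> 50% of the
component inside the WMH mask), size gates (< 2 voxels, > 3000 mm³), and
roundness (elongation < 1.5). The categories follow the usual manual QC
criteria (lacunes and small WMHs are round; pAs are linear); the numeric
thresholds are package defaults, config-exposed, because the literature
states the categories but not numbers. "Clustering" and
"anatomical-location" exclusions are supported as user-supplied predicate
functions, off by default, for the same reason. Filtering is idempotent
and every removal carries a machine-readable reason.

Superficial-WM depth uses Laplacian distance mapping: the Laplace equation
is solved over the WM interior (6-neighbor stencil, spacing-weighted,
direct sparse solve) with Dirichlet values 0 at the gray-matter boundary
and 1 at the deep boundary, and the harmonic potential $\phi$ is converted
to metric depth as $\phi \times (d_{GM} + d_{deep})$, the per-voxel total
path length approximated by the sum of Euclidean distances to the two
boundaries. On slab geometry this equals streamline integration exactly;
we chose it over streamline tracing for robustness and simplicity. WM
regions touching neither boundary are flagged missing. Cortical ROI labels
propagate into WM voxels with depth ≤ 5 mm by k-nearest-neighbor majority
vote (k = 5 default; k is not fixed by any reference, so it is
config-exposed; ties break toward the lower label).

Per ROI, the four largest components (by volume; ties by component id)
enter the metrics — large components are the partial-volume guard, since
their diameters exceed the DWI voxel size. `optimize_n()` reproduces the
selection analysis behind that default: for each candidate n it sums the
absolute t statistics of covariate-adjusted associations between the
metrics and clinical variables and reports the maximizing n with the
subject-inclusion fraction; exact ties resolve toward smaller n (greater
inclusion). Whether components should be ranked by volume or diameter is
not settled; volume is the implemented choice.

## Metric extraction

ROI metrics are unweighted means over the voxels of the selected
components ("averaged across voxels", not across components). WM-FWVF
excludes all WMH and pAs voxels before averaging, and the tests verify the
exclusion by explicit voxel bookkeeping. Whole-brain pAs metrics pool the
per-ROI selections by default; a switch re-selects the n largest globally
instead — the right pooling is genuinely ambiguous, and the default keeps
per-ROI and whole-brain analyses consistent. Classifier feature sets are
fixed-order matrices (pAs: 6 columns; WM: 3; pVs: 1; combinations; PET
SUVR sets when supplied) with listwise deletion per set, so a subject
missing only the ALPS index drops out of pVs analyses alone.

## Statistical battery

Standardized-β regressions z-score outcome and predictor and enter
covariates raw; p-values are two-sided from the t distribution, and FDR
correction (Benjamini–Hochberg, via `stats::p.adjust`) is applied within
one family — one anatomical compartment — at a time. ANCOVA is the
added-last F test from nested linear models; with no covariates it is
one-way ANOVA exactly. Tukey HSD uses the studentized range on
covariate-adjusted means (Tukey–Kramer for unequal groups); at k = 2 it
equals the pooled t-test. The nonparametric fallback rank-transforms the
outcome (mid-ranks) before the same F test, with pairwise Wilcoxon
rank-sum tests post hoc.

Classification uses seeded stratified k-fold cross-validation
(defaults 10 folds, seed 42) with pooled out-of-fold decision scores and
one ROC/AUC per model — pooling is required so that DeLong comparisons
operate on one paired score vector per model. The DeLong test itself is
implemented from the structural components (midrank estimator, covariance
of the placement values); the tests cross-check it against both `pROC` and
a seeded permutation oracle. Classifiers are delegated (logistic GLM
default; SVMs and gradient boosting optional).

Serial mediation fits the three OLS equations
($M_1 \sim X$; $M_2 \sim X + M_1$; $Y \sim X + M_1 + M_2$, all plus
covariates) and the total-effect equation, reports the serial indirect
effect $a_1 a_2 b$, and builds its CI by case-resampling bootstrap
(default 5000 draws) with the bias-corrected (BC, not BCa) percentile
method — bias correction without acceleration, which is what
"bias-corrected 95% CI" conventionally denotes. Significance is "CI
excludes zero". The OLS decomposition
$c = c' + a_1 d_1 + a_3 b + a_1 a_2 b$ holds to numerical precision and is
asserted in the tests. Variables can be analyzed raw or z-scored
(`standardize`); both conventions appear in practice, and path
coefficients on raw scales depend on units (a blood-pressure coefficient
of $2\times10^{-5}$ on a diffusivity scale of $10^{-3}$ is not comparable
across studies), so the flag is explicit rather than hidden.

Phenotype derivations: MAP = (2·diastolic + systolic)/3; amyloid-PET
positivity by strict thresholds (florbetapir composite SUVR > 1.11,
florbetaben > 1.478) — the AV45 cutoff in circulation contains a typo
("0.1.11"); 1.11 is the standard published value and the implemented one.

## Synthetic data: what it does and does not emulate

`render_phantom()` builds a WM slab with tubular pAs structures along z
(high anisotropic free-water content: FWVF 0.9, fluid AD 4.0e-3 along the
tube) against low-free-water WM (FWVF 0.1) and spherical WMH blobs
(FWVF 0.4), a gray-matter boundary face, a deep boundary face and a
two-label cortical atlas, rendered through the forward model with seeded
Rician noise. `make_cohort()` draws phenotypes from marginals matched to
published summary statistics of a cognitively normal aging cohort, plants
standardized CMS effects on the pAs metrics, diagnostic-group offsets on
FWVF, and a serial-mediation chain generated on standardized scales and
mapped affinely onto physiological units (affine maps leave standardized
path coefficients unchanged, so recovery is tested with
`standardize = TRUE`).

`make_component_cohort()` is the fixture for the n-selection procedure:
only the four largest components carry the subject-level signal, the
per-component measurement noise is twice the signal SD (so pooling all
four is materially better than fewer), and the component-count
distribution keeps ~98% of subjects at n = 4 falling to ~20% at n = 8 —
the sensitivity/inclusion trade-off the procedure navigates.

What passing tests on these generators shows: the estimators recover what
they are meant to estimate under the stated noise model, the pipeline's
plumbing (masks, exclusions, selections, label propagation) is exact, and
the statistics match independent oracles. What it does not show: behavior
under motion, eddy-current or susceptibility artifacts, imperfect
registration, segmentation error, anatomically realistic fiber
configurations, or partial-volume geometry more complex than tubes in a
slab — real-data claims need real data.

## Problem sizes and runtime

The shipped validation uses 200 noiseless voxels for parameter recovery, a
12×12×9 phantom (1008 masked voxels) at SNR 30 for map accuracy, 100
voxels for the isotropic limit, 300 subjects for the selection procedure,
1000 random vectors for the FDR oracle, 10⁴ permutations for the DeLong
oracle, and 200 replicates at 1000 bootstrap draws for mediation null
coverage. These sizes make every Monte-Carlo bound comfortable while
keeping the whole validation run under ten minutes on one CPU.

## Known limitations

- Two compartments only; no exchange, no intra/extra-axonal separation,
  no Rician likelihood (the floor correction is a moment fix, not full
  noise modeling).
- The spatial anchor pass assumes locally homogeneous tissue; across
  tissue boundaries (e.g. the rim of a lesion) the anchors mix
  populations and can bias small structures.
- ALPS ROI placement, pAs segmentation and WMH segmentation are consumed
  as inputs, not computed.
- The Laplacian depth's metric conversion is exact on slabs and an
  approximation on curved geometry (it underestimates path length where
  streamlines bend).
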
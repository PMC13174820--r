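# glymphr

Multi-compartment glymphatic metrics from multi-shell diffusion MRI.

The brain's waste-clearance (glymphatic) pathway has three limbs:
cerebrospinal fluid influx along periarterial spaces (pAs), exchange with
interstitial fluid in the white-matter (WM) parenchyma, and efflux along
perivenous spaces (pVs). `glymphr` quantifies all three from a single
multi-shell diffusion-weighted MRI acquisition:

- **Periarterial fluid mobility** — an anisotropic bi-tensor ("tissue +
  free water") model is fitted voxelwise and the fluid tensor's axial
  diffusivity (FWAD) and volume fraction (FWVF) are averaged over segmented
  pAs components;
- **Parenchymal free water** — WM-FWVF over WM with lesion (WMH) and pAs
  voxels excluded;
- **Perivenous integrity** — the DTI-ALPS index from directional
  diffusivities in projection/association fiber ROIs.

It is aimed at neuroimaging researchers studying aging, cardiometabolic
risk and Alzheimer's disease, and ships the full downstream statistical
battery used in such studies plus synthetic phantom and cohort generators
so every step is testable without scanner data.

## The model

The signal of voxel with gradient direction $g$ and b-value $b$ is

$$S(b, g) = S_0\left[f\,e^{-b\,g^\top D_f\,g} + (1-f)\,e^{-b\,g^\top D_t\,g}\right]$$

where $f$ is the free-water volume fraction (FWVF), $D_f$ the fluid tensor
and $D_t$ the tissue tensor. Unlike conventional free-water-elimination
DTI, which forces $D_f = d_{\text{free}} I$, the fluid tensor here is a
full symmetric PSD tensor, so the directionality of perivascular fluid
(FWAD $= \lambda_1(D_f)$, FWRD, FWMD, FWFA) is estimable. Estimation is
staged: log-linear single-tensor fit, isotropic free-water-elimination fit
(grid over $f$ + Levenberg–Marquardt), then the anisotropic fit with both
tensors parameterized by Cholesky factors and $f$ by a logistic transform,
with physical eigenvalue bounds enforced by penalty. Volume fitting adds a
b0-based Rician noise-floor correction and a spatial pass that anchors
compartment mean diffusivities to neighborhood medians.

The DTI-ALPS index is
$\mathrm{ALPS} = \operatorname{mean}(D_{xx}^{\text{proj}}, D_{xx}^{\text{assoc}}) / \operatorname{mean}(D_{yy}^{\text{proj}}, D_{zz}^{\text{assoc}})$.

Downstream statistics: covariate-adjusted standardized-β regression with
Benjamini–Hochberg FDR, ANCOVA with Tukey HSD and rank-based fallbacks,
stratified 10-fold cross-validated classification with pairwise DeLong AUC
tests, and serial two-mediator bootstrap mediation
($X \to M_1 \to M_2 \to Y$, indirect effect $a_1 a_2 b$ with
bias-corrected bootstrap CI).

## Worked example

Simulate a voxel with 30% anisotropic free water on the HCP-Aging
two-shell scheme and recover it:

```r
library(glymphr)
scheme <- make_scheme("hcpa")   # 6 b0 + 45 @ b=1500 + 45 @ b=3000

truth <- bitensor_voxel(S0 = 100, f = 0.3,
                        D_fluid  = axial_tensor(c(0, 0, 1), 3.8e-3, 2.6e-3),
                        D_tissue = axial_tensor(c(0, 1, 0), 1.5e-3, 0.4e-3))
fit <- fit_bitensor(simulate_signal(truth, scheme), scheme)
fit
#> Bi-tensor fit (anisotropic)
#>   S0 = 100, FWVF (f) = 0.3000
#>   fluid : AD 3.800e-03  RD 2.600e-03  MD 3.000e-03  FA 0.227 (mm^2/s)
#>   tissue: AD 1.500e-03  RD 4.000e-04  MD 7.667e-04  FA 0.686 (mm^2/s)
#>   RSS 1.357e-27, converged: TRUE, iterations: 6
```

The planted FWVF (0.30) and fluid axial diffusivity (3.8e-3 mm²/s along
the tube axis) are recovered exactly on noiseless data.

Cohort-level analysis on a synthetic cohort with planted effects:

```r
coh <- make_cohort(cohort_spec(n = 200), seed = 1)
d <- merge(coh$features, coh$pheno, by = "subject")

standardized_beta("pas_FWAD_wholebrain", "bmi", c("age", "sex"), d)
#> standardized beta = -0.4746 (t = -7.507, p = 2.08e-12, n = 200)

serial_mediation(d$diastolic, d$pas_FWAD_precuneus,
                 d$abeta_suvr_precuneus, d$moca,
                 covariates = d[, c("age", "sex")],
                 n_boot = 1000, seed = 42, standardize = TRUE)
#> Serial mediation X -> M1 -> M2 -> Y (n = 200 )
#>   a1 = 0.7529  a2 = 0.6436  b = 0.6201
#>   total c = 0.2858  direct c' = 0.1993
#>   serial indirect a1*a2*b = 0.3005, BC 95% CI [0.2129, 0.4183] *
```

The negative BMI–FWAD association and the significant serial indirect
pathway (diastolic blood pressure → periarterial FWAD → amyloid SUVR →
cognition) are the structures the generator plants.

A command-line front end covering the whole pipeline
(`simulate`, `fit`, `alps`, `pas`, `extract`, `stats`, `classify`,
`mediate`) is installed at `system.file("cli", "glymphr.R", package =
"glymphr")`.

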
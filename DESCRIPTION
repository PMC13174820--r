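Package: glymphr
Title: Multi-Compartment Glymphatic Metrics from Multi-Shell Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies glymphatic function across periarterial, white-matter
    and perivenous compartments from multi-shell diffusion-weighted MRI. Fits
    an anisotropic bi-tensor (tissue + free-water) diffusion model voxelwise,
    computes free-water volume fraction and fluid-tensor diffusivity maps,
    the DTI-ALPS perivenous index, perivascular-space component morphometry
    with Laplacian depth mapping and ROI assignment, subject-level metric
    extraction, and the accompanying statistical battery (standardized-beta
    regression with FDR control, ANCOVA with Tukey and rank-based fallbacks,
    stratified cross-validated classification with DeLong AUC comparisons,
    and serial two-mediator bootstrap mediation). Includes synthetic phantom
    and cohort generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    e1071,
    xgboost,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
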
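Package: dtialps
Title: Diffusion Tensor Image Analysis Along the Perivascular Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies glymphatic system function from diffusion MRI via the
    DTI-ALPS (diffusion tensor image analysis along the perivascular space)
    index. Fits diffusion tensors from diffusion-weighted volumes by weighted
    least squares, derives fractional anisotropy and mean diffusivity maps,
    places spherical projection- and association-fibre regions of interest at
    the lateral ventricle body, and computes left, right and bilateral ALPS
    indices with automated placement quality control. Includes generators for
    digital periventricular tensor phantoms with known ground-truth indices
    and for synthetic genetic frontotemporal dementia cohorts, together with
    the cohort-level statistics used in ALPS studies: covariate-adjusted
    group comparisons with false-discovery-rate corrected pre-defined
    contrasts, association models with clinical severity and plasma markers,
    Z-score stratification, and linear mixed models of longitudinal disease
    progression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    lme4,
    emmeans,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
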
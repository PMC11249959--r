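---
title: "DTI-ALPS: model, synthetic data and statistical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTI-ALPS: model, synthetic data and statistical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The diffusion model

Each voxel carries a symmetric diffusion tensor `D` (mm²/s) linking the
diffusion-weighted signal to the acquisition via
`S = S0 * exp(-b * g' D g)`, with b-value `b` (s/mm²) and unit gradient
direction `g`. `fit_tensor()` estimates the six unique tensor components
and `log S0` per voxel from the log-linearised model in two stages:
an ordinary least-squares pass, then a single weighted pass with weights
equal to the squared predicted signals. This is the standard WLS tensor
estimator: the log transform makes the noise variance approximately
proportional to `1/S²`, so weighting by `S²` restores efficiency without
iterative nonlinear fitting, and matches what DTIFIT-class tools do. OLS
is available (`method = "ols"`) for comparison.

Numerical edge cases are handled explicitly rather than silently:

* volumes with non-positive signal are dropped per voxel; a voxel with
  fewer than 7 usable volumes (or a rank-deficient remaining design) is
  *unfittable* — zero tensor, flagged;
* tensors with negative eigenvalues after the fit are projected onto the
  PSD cone (negative eigenvalues clamped to 0) and flagged, which keeps
  FA and MD defined while preserving QC visibility;
* FA is computed through the rotation-invariant component form, which is
  algebraically identical to the eigenvalue expression
  `sqrt(3/2) * ||λ − mean(λ)|| / ||λ||` but needs no per-voxel
  eigendecomposition; zero tensors map to FA = 0.

## Axis convention and the ALPS index

All world coordinates are RAS millimetres with `x` = left–right,
`y` = anterior–posterior, `z` = head–foot; non-RAS NIfTI inputs are
reoriented on load. The index assumes perivascular flow along the
medullary veins (x-axis), projection fibres along z, association fibres
along y, giving per hemisphere

`ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`

and the bilateral index as the mean of the two hemispheres. The
literature on this method contains an internal inconsistency in its
narrative axis naming (projection fibres are once described as the y-axis
and once as running in the z direction); we implement the convention that
is consistent with the index formula itself — projection fibres along
head–foot z (denominator `Dyy` there), association fibres along
anterior–posterior y (denominator `Dzz` there) — and note the
discrepancy here rather than resolving it.

ROI centres are deliberately *inputs*, not constants: published template
coordinates for the four spheres live in supplementary material we do not
reproduce, so the package never invents template-space coordinates as
ground truth. The shipped defaults are defined in the synthetic phantom's
own coordinate frame. Default radius is 5 mm. Voxel membership uses the
voxel-centre-in-sphere rule with a closed boundary (distance ≤ radius):
deterministic and grid-resolution independent.

### Placement quality control

Clinical ALPS studies exclude subjects whose ROIs land outside their
fibre regions after registration, by visual inspection. `qc_placement()`
is a reproducible proxy: an ROI fails if mean FA < 0.15 (not in coherent
white matter), if fewer than 50% of voxels have principal eigenvectors
within a 30° cone of the expected fibre axis (projection → z,
association → y), or if fewer than 10 voxel centres fall inside the
sphere. All thresholds are configurable; a QC failure flags the result
but never suppresses the index.

## What the phantom emulates

`make_phantom()` builds the periventricular geometry the index assumes:
per hemisphere a projection-fibre block
(`diag(λ_perp + ε, λ_perp, λ_par)`) medial to an association-fibre block
(`diag(λ_perp + ε, λ_par, λ_perp)`) inside isotropic background. The
perivascular component is the increment `ε` on `Dxx` in both blocks, so
the ground-truth index is `(λ_perp + ε)/λ_perp` in closed form. Defaults
λ_par = 1.7×10⁻³, λ_perp = 0.4×10⁻³, ε = 0.12×10⁻³ mm²/s give FA ≈ 0.68
in the fibre blocks and a true index of 1.3 — the healthy range. Setting
`ε = 0` produces the impairment floor of exactly 1.0. Optional Gaussian
noise on the diagonal entries (re-projected onto the PSD cone) and
Rician-noise DWI simulation (`simulate_dwi`, default protocol 5 b0 + 61
directions at b = 1000 s/mm², spherical-Fibonacci directions) exercise
the fitting path.

The phantom does **not** emulate real anatomy: no partial-volume or CSF
contamination, no registration error, no scanner-specific artifacts, no
spatially varying fibre dispersion. Passing phantom tests therefore shows
that the index computation is correct given correctly placed ROIs in
coherent tissue — not that the index is robust to the registration and
quality problems that cause the real-world exclusions QC is meant to
catch.

## What the cohort generator emulates

`make_cohort()` reproduces the statistical skeleton of a multi-site
genetic-FTD cohort: eight groups (young/old non-carriers; presymptomatic
and symptomatic *C9orf72*, *GRN*, *MAPT* carriers) with study-default
sizes 50/33/68/88/43/44/31/17 (374 subjects, 291 carriers), per-group
bilateral ALPS marginal means (1.32/1.29/1.28/1.32/1.28/1.19/1.24/1.21)
and demographics, plus association slopes linking ALPS to disease
severity (CDR-FTLD, default −1.16 per unit ALPS), years to expected
onset (−9.94, presymptomatic), and natural-log plasma NfL (−0.28) and
GFAP (−0.10).

Choices worth knowing about:

* **Subject-level dispersion.** Published group summaries report standard
  errors of estimated marginal means; subject SDs are derived as
  `SE * sqrt(n)` per group (0.14–0.19 here). No within-group SD is
  published, so this is a declared assumption. A consequence is that the
  symptomatic-vs-old-non-carrier comparison is a *moderate* effect at
  these group sizes: its sign is stable but FDR significance holds only
  in a fraction of simulated cohorts, which the tests assert as such.
* **Severity generation.** CDR-FTLD is generated directly from the
  marginal association model `cdr = a + β·ALPS + noise` over carriers. A
  single linear generator cannot simultaneously reproduce the published
  stage means (≈0.1 presymptomatic vs ≈1.8 symptomatic) *and* the
  published slope −1.16 under the same covariate-adjusted model — the
  stage gap per unit ALPS difference is an order of magnitude larger than
  the slope. Because the package's parameter-recovery guarantees are
  about the slope, the slope wins; stage labels follow group membership,
  and simulated CDR stage means are compressed relative to a real cohort.
* **Latent vs instrument scale.** Severity is generated on a continuous
  latent scale (`cdr_ftld_latent`, used by the statistics by default) and
  also reported rounded to the instrument step of 0.5 and floored at 0
  (`cdr_ftld`), mirroring the quasi-continuous treatment of CDR-FTLD in
  the models while keeping an instrument-faithful column.
* **Sites.** Imaging site is uniform over 5 levels and plasma analysis
  site over 2 — the covariate structure the models need; the true
  multi-site composition is not public.
* **Longitudinal design.** Carriers receive 1–6 visits with probabilities
  chosen so that roughly 64% have at least two evaluations and the
  expected total is ≈2.3 visits/carrier, at 1-year spacing. Trajectories
  are `baseline + (stratum slope + subject random slope)·t + random
  intercept + noise`, stratum slopes 0.20/0.05/−0.01 per year for
  low/average/high baseline ALPS (Z < −1, |Z| ≤ 1, Z > 1 against the
  pooled non-carrier mean and sample SD).

## Statistical methods

* **Group comparisons** are linear models `outcome ~ group + age + sex +
  site`; estimated marginal means use covariate means for continuous and
  observed marginal proportions for categorical covariates (the
  publication style does not state its grid; proportional weighting is
  the least surprising choice). Only pre-defined contrast families are
  tested — 3 stage-level, 9 mutation×stage — and Benjamini–Hochberg FDR
  is applied within a family, never pooled across analyses.
* **Boundary rule.** Z-scores of exactly ±1 go to "average": the strata
  are defined by strict inequalities, so the boundary belongs to neither
  tail. The non-carrier reference uses the pooled sample SD of all
  non-carriers (the estimator is otherwise unspecified).
* **Association models** are linear with the stated covariates; plasma
  outcomes are natural-log transformed, with non-positive values a hard
  error (they indicate data corruption, not biology). Complete-case
  analysis per model.
* **The progression model** is
  `cdr ~ time * stratum + age + sex + baseline_cdr + site +
  (1 + time | subject)`, fitted by REML with lme4. Fixed effects,
  per-stratum slopes (time coefficient plus interaction) and their
  pairwise contrasts use Wald z statistics; the stratum×time interaction
  is a 2-df Wald chi-square. The degrees-of-freedom approximation is
  deliberately asymptotic — the reference analysis does not state its DF
  method, and Wald z is portable and honest about being approximate. In
  simulation this costs a little anticonservatism at these sample sizes
  (observed interaction type-I error near 5% over 200 null replicates in
  the acceptance suite). Singular random-effect fits are flagged, not
  hidden.
* **FDR.** Step-up BH via `p.adjust`. Note that BH is *not* idempotent on
  general already-adjusted vectors (re-applying the step-up to a strictly
  increasing adjusted vector inflates it); only fully tied vectors are
  fixed points, and the tests assert exactly the properties that hold:
  monotonicity, order preservation, permutation equivariance.

## Problem sizes and determinism

The shipped tests run the tensor round trip on a 20³ grid with the 66-
volume default protocol, phantoms at 56×36×36 voxels, cohorts at the
study sizes (374 subjects), 100 recovery and 500 null replicates for the
cross-sectional slope, and 200 null replicates for the longitudinal
interaction — sizes chosen so the whole suite exercises every claim in
minutes on one CPU. All generators are seeded; the pipeline derives
per-stage seeds from one global seed by a fixed affine hash, so
`run_all()` is byte-reproducible, and the run manifest records the config
hash and output file checksums (no timestamps, by design).

## Limitations

Upstream preprocessing — denoising, eddy-current/motion correction, and
registration to a standard FA template — is out of scope: inputs are
assumed co-registered, and the ROI set is interpreted in the input's
world space. Only the four-ROI bilateral scheme is implemented (no
regional or whole-brain ALPS variants). The synthetic cohort reproduces
marginal structure and generating slopes, not the joint distribution of
a real cohort; in particular ALPS is generated independently of age and
site within groups, so covariate adjustment cannot be stress-tested for
confounding with these generators alone.
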
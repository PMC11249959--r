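# dtialps

Glymphatic system quantification from diffusion MRI via the **DTI-ALPS
index** (diffusion tensor image analysis along the perivascular space),
with the cohort statistics used in studies of genetic frontotemporal
dementia (FTD), and synthetic phantom/cohort generators that make the whole
pipeline testable end to end without access to clinical data.

## The method

At the level of the lateral ventricle body, three tissue orientations
coexist at right angles: medullary veins (and their perivascular spaces)
run left–right (world *x*), projection fibres run head–foot (*z*), and
association fibres run anterior–posterior (*y*). In a projection-fibre
region, diffusivity along *x* is perpendicular to the fibres, so any excess
of D<sub>xx</sub> over the fibre-perpendicular reference D<sub>yy</sub>
reflects water movement along the perivascular space; likewise for the
association region with reference D<sub>zz</sub>. The index per hemisphere
is

```
ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

with the bilateral index the average of the left and right values. An index
near 1.0 means no measurable perivascular component (impairment); healthy
periventricular white matter typically yields ≈ 1.3.

The package provides:

* **Tensor fitting** (`fit_tensor`): two-stage weighted least squares on
  log signals, with FA/MD maps (`fa_map`, `md_map`) and NIfTI + bval/bvec
  I/O (`read_dwi`, `read_tensor`, ...).
* **ALPS computation** (`compute_alps`): 5 mm spherical ROIs in world
  coordinates (`sphere_roi`, `roi_set`), voxel-centre rasterization,
  per-ROI axis diffusivities, and automated placement QC (`qc_placement`)
  replacing visual inspection with FA, eigenvector-alignment and
  voxel-count thresholds.
* **Synthetic data** (`make_phantom`, `simulate_dwi`, `make_cohort`,
  `make_longitudinal`): periventricular tensor phantoms with closed-form
  ground truth, Rician-noise DWI simulation, and a GENFI-like cohort
  (374 subjects: 291 mutation carriers across *C9orf72*/*GRN*/*MAPT* ×
  presymptomatic/symptomatic, 83 non-carriers) with configurable
  ALPS–severity association slopes and stratum-specific longitudinal
  progression.
* **Cohort statistics** (`adjusted_group_comparison`, `association_model`,
  `stratify_alps`, `lmm_progression`, `describe_cohort`, `fdr_adjust`):
  covariate-adjusted estimated marginal means with pre-defined,
  FDR-corrected contrast families (3 stage-level, 9 mutation×stage),
  association models with optional log-transformed plasma outcomes,
  Z-score stratification against the non-carrier reference, and a linear
  mixed model of longitudinal severity with random intercepts and slopes.
* **Pipeline** (`cmd_simulate`, `cmd_alps`, `cmd_stats`, `run_all`, plus
  the `exec/dtialps` command-line wrapper): YAML configuration with schema
  validation, per-stage seeds derived from one global seed, run manifests
  with file hashes, and deterministic JSON/text reports.

## Worked example

```r
library(dtialps)

# a noisy digital phantom whose true bilateral ALPS is 1.3
ph  <- make_phantom(phantom_spec(tensor_noise_sd = 2e-5, seed = 42))
res <- compute_alps(ph$tensor, ph$rois)
res
#> <alps_result>  left 1.3011  right 1.2979  bilateral mean 1.2995
#>   QC: pass

# a synthetic cohort with the study's group structure
d <- add_stage4(make_cohort(cohort_spec(seed = 42)))
association_model(d[d$mutation != "NC", ], "cdr_ftld_latent", "alps")
#> <assoc_result> cdr_ftld_latent ~ alps: beta = -1.104 (SE 0.131), p = 2.186e-15, n = 291

v <- make_longitudinal(d, longitudinal_spec(seed = 43))
lmm_progression(v, d)
#> <lmm_fit> cdr_ftld_latent, 291 subjects, 691 visits (singular fit)
#> Per-stratum annual slopes:
#>  stratum estimate     se      z        p
#>      low   0.2186 0.0166 13.185 1.07e-39
#>  average   0.0461 0.0098  4.706 2.53e-06
#>     high  -0.0148 0.0204 -0.728 4.67e-01
```

The recovered phantom index (1.2995) sits within noise of the closed-form
truth 1.3; the cross-sectional slope estimate (−1.10 ± 0.13) covers the
generating value −1.16; and the three progression slopes bracket their
generating values 0.20 / 0.05 / −0.01 CDR-FTLD units per year — subjects
with low baseline ALPS worsen fastest, those with high ALPS stay flat.

Full pipeline from the shell:

```sh
exec/dtialps run-all --seed 1 --out my-run
```

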
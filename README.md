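# petlesionsim

Synthetic lesion insertion and attenuation-correction (AC) evaluation for
PET, as a self-contained R simulator.

## What it is for

Attenuation correction is the largest single correction in PET image
reconstruction: the reconstruction must compensate the loss of 511 keV
photon pairs along each line of response by `exp(-∫ μ dl)`. On PET/MR
systems the attenuation map is derived from Dixon water/fat segmentation,
which cannot see cortical bone; bone voxels receive the soft-tissue
coefficient and lesion SUVs near bone are biased low relative to CT-based
AC (CTAC, the ground truth).

A lesion insertion tool quantifies this with known truth: a spherical
lesion of known activity is rasterized in image space, forward-projected
through the PET system model (attenuation, normalization, count scaling,
Poisson noise), added to an acquired sinogram, and the hybrid is
reconstructed like patient data — once per AC hypothesis, from the
identical sinogram, so any image difference is attributable to the AC
method alone.

The package is aimed at physicists and methods developers who want to
exercise AC-evaluation methodology (or teach it) without scanner data: it
generates pelvis-like digital phantoms (tissue labels, activity in kBq/mL,
CT numbers), derives CTAC and bone-free Dixon-style MRAC μ-maps,
forward-projects and reconstructs with OSEM (2 iterations, 16 subsets,
image-space PSF), and computes the evaluation statistics:

* **SUV Error Ratio** per VOI: `mean(SUV_MRAC) / mean(SUV_CTAC)`;
* **Lesion Error Ratio** per matched contralateral pair: original ratio ÷
  synthetic ratio (unity ⇔ faithful insertion);
* voxel-wise differences `100·(SUV_MRAC − SUV_CTAC)/SUV_CTAC` with μ, σ,
  `RMSE = √(μ²+σ²)` and extreme-value summaries per VOI;
* Bland–Altman limits of agreement and OLS trend diagnostics.

User-supplied co-registered volumes (NIfTI) are accepted in place of the
built-in phantoms.

## Worked example

Four anatomical target archetypes, one 12 mm / 5000 kBq/mL lesion each,
reconstructed under CTAC and bone-free MRAC without count noise:

```r
library(petlesionsim)
grid    <- voxel_grid(c(128, 128), 3)          # 3 mm voxels, 384 mm FOV
phantom <- make_pelvis_phantom(grid, background_kbq_ml = 5, seed = 1)
res     <- run_targeted_study(phantom, noise = FALSE, seed = 1)
res$table[, c("site", "bone_fraction", "mu_pct", "sigma_pct",
              "rmse_pct", "diff_max_pct")]
#>                site bone_fraction mu_pct sigma_pct rmse_pct diff_max_pct
#> 1        acetabulum         1.000  -6.11      3.19     6.89       -10.04
#> 2            sacrum         0.667  -4.10      4.46     6.06       -10.14
#> 3        lymph_node         0.000  -1.14      0.44     1.22        -2.29
#> 4 bladder_posterior         0.000  -1.77      0.55     1.85        -2.62
```

Reading the numbers: `mu_pct` is the mean voxel-wise SUV difference (%) of
MRAC relative to CTAC inside the lesion VOI. The acetabulum VOI sits
entirely in bone, so the missing bone in the MRAC map under-corrects its
LORs and the lesion reads ≈6% low on average (its largest single-voxel
discrepancy, `diff_max_pct`, is −10%); the sacrum VOI (two-thirds bone) is
intermediate; the two soft-tissue sites stay within ±2%.

The matched contralateral protocol checks the insertion tool itself — a
synthetic twin of each lesion, mirrored across the midline of a symmetric
phantom with matched size and contrast, must show the same AC error as its
original:

```r
cfg <- default_run_config()
cfg$validation1$n_phantoms <- 4L
cfg$validation1$n_lesions  <- 16L
v1 <- run_validation1(cfg)
#> mean Lesion Error Ratio 1.002 +/- 0.007 over 16 pairs
#> trend vs diameter: R^2 = 0.0001
#> <bland_altman> mean 0.001607, LoA [-0.01226, 0.01547], 16 pairs (94% within)
```

A cohort mean Lesion Error Ratio at unity with no diameter trend means the
synthetic lesions reproduce the originals' AC-error behaviour across the
9–40 mm size range.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
inst/cli/petlesionsim phantom     --config run.yaml --out phantom_dir
inst/cli/petlesionsim insert      --phantom phantom_dir --lesions lesions.csv --out study_dir
inst/cli/petlesionsim recon       --sinogram study_dir/hybrid_sinogram.tsv --phantom phantom_dir --mu mrac --out study_dir
inst/cli/petlesionsim validation1 --config run.yaml --out v1_out
inst/cli/petlesionsim validation2 --config run.yaml --out v2_out
```

Run configuration is a strict-schema YAML overlay on
`default_run_config()`; unknown keys are rejected. An example lives in
`inst/extdata/example_run.yaml`.

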
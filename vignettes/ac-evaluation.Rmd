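---
title: "Evaluating PET attenuation-correction methods with synthetic lesion insertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating PET attenuation-correction methods with synthetic lesion insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petlesionsim)
```

## The problem

Attenuation correction (AC) is the single largest correction applied in PET
image reconstruction: 511 keV annihilation photon pairs are lost to
absorption and scatter along each line of response (LOR), and the
reconstruction must compensate by the inverse of the survival probability
`exp(-∫ μ dl)`. On PET/CT systems the attenuation map μ comes from the CT
volume (CTAC) and is treated as ground truth. On PET/MR systems the map must
be derived from MR contrast; the widely deployed Dixon segmentation approach
classifies tissue as water- or fat-like and assigns one fixed attenuation
coefficient per class. Cortical bone, with its sub-millisecond T2*, is
invisible to the Dixon sequence and is mapped as soft tissue, so MR-based AC
(MRAC) systematically under-corrects near bone and the reconstructed
standardized uptake values (SUVs) of nearby lesions are biased low.

A synthetic lesion insertion tool makes this error measurable with known
ground truth: a spherical lesion of known activity is rasterized in image
space, forward-projected through the PET system model (attenuation, detector
normalization, count scaling, Poisson noise), added to an acquired emission
sinogram, and the hybrid is reconstructed exactly like patient data. Because
the same hybrid sinogram can be reconstructed under different AC hypotheses,
any difference between the images is attributable to the AC method alone.

This package is a self-contained simulator of that workflow: it generates
its own pelvis-like digital phantoms, so no patient or scanner data are
required, and it reproduces the two validation protocols used for such
tools — matched contralateral insertion and targeted insertion at anatomical
archetypes — together with their statistics.

## System model

The projection model is 2-D parallel-beam over a single axial slice:
`n_angles` views uniform on [0°, 180°) (default 96) and radial bins matched
to the voxel size. The forward projector is pixel-driven with linear
interpolation: each voxel centre projects to
`r = (x - cx) cos θ + (y - cy) sin θ` about the grid centre and deposits
voxel-area/bin-width into its two neighbouring radial bins, so line
integrals carry units of value × mm and every view conserves total activity
exactly. The back-projector is the exact matrix transpose. The projector is
assembled once per (grid, geometry) pair as a sparse matrix and cached.

A real cylindrical TOF scanner differs from this model in geometry
(curved detector rings, arc corrections), in physics (scatter, randoms,
dead time) and in the TOF likelihood. None of these mechanisms is required
to exercise AC errors; the parallel-beam model keeps every modelled effect
(attenuation, normalization, Poisson statistics, PSF) while remaining exactly
adjoint, which the EM update requires. Two consequences are documented
rather than modelled:

* the pipeline is trues-only (no scatter or randoms background);
* the reconstruction is non-TOF. TOF localization is known to dampen the
  quantitative consequences of a wrong μ-map, so the bias magnitudes
  produced here are expected to be larger than on a TOF system with the
  same anatomy. Sign structure and ordering, the quantities asserted by the
  package's checks, are unaffected.

Expected counts are
`λ = count_scale · norm · exp(-∫μ dl) · ∫activity dl`, and noisy
acquisitions draw one Poisson sample per bin under a fixed seed. The default
`count_scale` (0.46 counts per kBq/mL·mm) was set once so the reference
phantom (5 kBq/mL background, 128 × 128 at 3 mm, 96 angles) yields about
5 × 10⁵ true counts in the slice, a realistic single-slice count level for a
clinical FDG frame.

## Reconstruction

`osem()` implements ordered-subsets expectation maximization with the full
system model — attenuation factors of the chosen μ-map, normalization, count
scale and an isotropic Gaussian PSF applied in image space inside the
forward model and its adjoint. Defaults follow the modelled clinical
protocol: 2 iterations, 16 subsets. Angles are assigned round-robin
(angle *i* → subset *i* mod 16) and processed in fixed order; the initial
image is uniform; bins whose model forward projection falls below 1e-12 are
excluded from the ratio; the multiplicative update preserves non-negativity.
With one subset the update is the classical MLEM iteration, which the test
suite verifies against an independently written reference implementation.

The PSF is a separable, zero-padded Gaussian convolution (default FWHM
4.5 mm, a typical reconstructed resolution for whole-body PET). It is
hand-rolled rather than delegated to an image library because the OSEM
update needs the blur and its adjoint to match exactly; a symmetric kernel
with zero padding is self-adjoint by construction, whereas packaged blurs
make boundary choices that break the pairing.

One behaviour worth knowing: with few angles per subset, the fixed subset
ordering breaks exact left–right symmetry of the reconstruction — a
bilaterally symmetric sinogram does not yield a bitwise-symmetric image at
2 iterations × 16 subsets. This is a property of ordered subsets, not a
defect; the symmetry oracle in the tests therefore uses MLEM, and the
matched-cohort generator alternates lesion sides so any residual ordering
effect averages out across a cohort, as it would across patients.

## Phantoms

`make_pelvis_phantom()` builds co-registered tissue labels (air, fat, soft,
bone), activity (uniform background in all non-air tissue, default
5 kBq/mL) and a CT volume on one grid: an elliptical body with a
subcutaneous fat rim, thin mirrored iliac-wing analogs, compact acetabular
knobs and a midline sacral body. With `symmetric = TRUE` the label, activity
and CT volumes are exactly invariant under left–right mirroring about the
midsagittal plane, which is what makes contralateral insertion a controlled
experiment.

The bone structures are deliberately slender. The AC error of bone-free
MRAC scales with the cumulative bone chord crossed by each LOR; an axial
pelvis slice crosses centimetre-scale cortical paths, not the decimetre
blocks a naive "bone blob" would produce. The layout was calibrated once so
that the four target-site archetypes reproduce the qualitative error
structure of segmentation MRAC: VOIs inside bone are biased several percent
negative while soft-tissue VOIs stay within about ±2%. Class CT numbers
default to air −1000, fat −90, soft +40, bone +700 HU, with optional
Gaussian texture (default σ = 10 HU, clipped to preserve class invariants
and mirrored on symmetric phantoms).

`default_target_sites()` returns the four archetypes spanning bone-dominant
to soft-tissue-dominant VOI composition — acetabulum (bone fraction ≈ 1 at
the default grid), sacrum (intermediate), sidewall lymph node and posterior
bladder (both bone-free) — with the bone fraction of each 12 mm VOI measured
on the phantom.

What the generator does *not* emulate: organ-specific uptake, lesion
texture, respiratory or patient motion, continuous marrow/cortical density
gradients, and 3-D out-of-plane anatomy (the core pipeline is a single
axial slice; "spheres" are discs). Passing the package's checks therefore
demonstrates correctness of the insertion/reconstruction/evaluation
machinery under controlled conditions, not clinical realism of any
particular bias magnitude.

## Attenuation maps

`hu_to_mu_ctac()` applies the standard bilinear CT conversion:
`μ = μ_water (1 + HU/1000)` for HU ≤ 0 and `μ = μ_water + HU · slope_bone`
above water, with μ_water = 0.0975 cm⁻¹ and slope_bone = 5.64 × 10⁻⁵
cm⁻¹/HU, both overridable.

`derive_mrac_dixon()` assigns one fixed coefficient per class from a
*perfect* water/fat segmentation of the ground-truth labels, with bone
mapped to the soft-tissue coefficient — the defining bone-free property.
Using the true labels is a deliberate scope decision: the quantity under
study is the AC consequence of missing bone, not Dixon segmentation
fidelity.

The default Dixon coefficients are calibrated to the CTAC map evaluated at
the nominal class CT numbers (so fat ≈ 0.0887 cm⁻¹ and soft ≈ 0.0998 cm⁻¹
at the defaults) rather than fixed literature constants. Clinically deployed
segmentation MRAC is tuned so soft tissue reconstructs essentially
correctly; in a simulator whose ground truth *is* the CTAC map, assigning
soft tissue a coefficient that disagrees with its own CT-derived value by
several percent would add a global pseudo-error of ~5% to every VOI and
swamp the bone effect the method isolates. Any fixed pair (for example the
conventional water 0.0975 / fat 0.086 cm⁻¹) can be supplied through the
`coefficients` argument or the config.

## The two validation protocols

**Matched contralateral insertion** (`run_matched_study()`,
`run_validation1()`): original lesions are simulated in one hemipelvis of a
symmetric phantom; each lesion's mean VOI value is measured on the CTAC
reconstruction; a synthetic twin with matched diameter and matched contrast
is inserted at the mirrored centre; the hybrid sinogram is reconstructed
under CTAC and MRAC. Per pair, the SUV Error Ratio
(mean SUV_MRAC / mean SUV_CTAC) is computed for the original and for the
synthetic lesion, and their quotient is the Lesion Error Ratio. If insertion
is faithful, mirrored anatomy guarantees both members suffer the same AC
error and the cohort mean Lesion Error Ratio is unity. The cohort summary
also reports the ratio-versus-diameter trend (expected flat) and
Bland–Altman agreement of the two ratios (raw differences; the sample SD
with divisor N−1 sets the 1.96·SD limits).

Matched "contrast" is interpreted as the reconstructed CTAC VOI mean (the
measurable quantity on patient data), switchable to the true inserted
concentration via `contrast_from = "true"`. The inserted lesion's sinogram
is attenuated by the ground-truth CTAC map in both branches — the data are
generated by physics, the AC hypothesis enters only at reconstruction — and
`lesion_mu = "recon"` switches to the alternative reading in which each
reconstruction's own μ-map also generates its lesion data. Base-acquisition,
original-lesion and synthetic-lesion noise seeds are distinct and recorded.

**Targeted insertion** (`run_targeted_study()`, `run_validation2()`): one
12 mm, 5000 kBq/mL lesion per target site per phantom (4 phantoms × 4 sites
by default), each insertion reconstructed from the identical hybrid
sinogram under both AC methods. Per VOI, every voxel contributes
`100 · (SUV_MRAC − SUV_CTAC) / SUV_CTAC`, summarised by mean μ, population
standard deviation σ (the VOI voxel population is exhaustive, hence divisor
N), `RMSE = √(μ² + σ²)` (an exact identity, asserted to 1e-12), the maximum
absolute difference, and the signed largest-magnitude difference reported in
the per-site box plot. Voxels with SUV_CTAC below 1e-6 are excluded and
counted. The protocol defaults to noise-off, which isolates the AC effect
and makes the per-site sign structure deterministic; Poisson noise can be
enabled to study its additional spread.

```{r targeted, eval = TRUE}
cfg <- default_run_config()
cfg$validation2$n_phantoms <- 1L
res <- run_validation2(cfg)
res$site_summary[, c("site", "bone_fraction", "mu_pct", "sigma_pct",
                     "rmse_pct")]
```

The bias is negative wherever missing bone intersects the VOI's LORs,
largest for the bone-dominant acetabulum VOI, intermediate at the sacrum,
and near zero (|μ| < 2%) at the two soft-tissue sites.

## Numerical and design choices

* **Angles**: 96 views. The subset count must divide the number of views
  for the round-robin partition, and 96 = 6 × 16 angles pairs naturally
  with the 16-subset protocol.
* **Grid**: 128 × 128 at 3 mm is the reference desk-scale grid; the
  clinical 256-matrix geometry is accepted through the config. Unit tests
  run on 32–64 voxel grids; the cohort studies and the acceptance script
  use the full 128 grid (a matched 16-pair cohort runs in well under a
  minute per seed).
* **Seeds**: every stochastic operation takes an explicit seed;
  sub-seeds are derived deterministically and kept below 2³¹. Identically
  configured reruns are byte-identical, which the suite asserts on the
  emitted CSV/JSON.
* **Division guards**: EM ratios skip bins with model value < 1e-12;
  sensitivity divisions are floored at the same epsilon; VOI ratio
  statistics require a strictly positive CTAC mean.
* **Degenerate lesions**: a lesion too small to capture a voxel centre
  fills its nearest voxel, so no insertion silently vanishes.
* **SUV convention**: `SUV = activity / (dose/weight)` with dose treated as
  decay-corrected to scan start (the decay convention is not modelled).
* **No multiplicity correction**: the evaluation statistics are
  descriptive.

## Known limitations

Single-slice 2-D geometry; trues-only data; non-TOF reconstruction (bias
magnitudes are upper bounds relative to TOF systems); uniform-background
phantoms without organ uptake; perfect Dixon segmentation; spherical lesions
without texture. These bound what the simulator's numbers mean: the
*machinery* (insertion fidelity, AC isolation, statistics) is validated
exactly, while absolute bias magnitudes are anatomy- and system-dependent
and should not be read as predictions for any particular scanner.
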
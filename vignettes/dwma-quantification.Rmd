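---
title: "Objective DWMA quantification: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective DWMA quantification: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diffuse white matter abnormality (DWMA, historically "diffuse excessive
high signal intensity") is a diffusely hyperintense appearance of cerebral
white matter on T2-weighted MRI of very preterm infants at term-equivalent
age. Visual grading of DWMA is unreliable (intra-rater kappa in the 0.4
range) and has repeatedly failed to predict outcomes; an objective,
intensity-based volume measurement does predict motor and cognitive
development. `neodwma` implements such an objective quantification
pipeline end to end, together with the prognostic statistics used to
evaluate it, and a synthetic-data layer that makes every stage testable
without any patient data.

## The quantification model

The pipeline runs in a fixed order on a T2w volume with a co-registered
probabilistic tissue atlas:

1. **Working brain mask.** Voxels whose summed atlas tissue prior
   (CSF + GM + WM) reaches `mask_threshold` (default 0.9), reduced to the
   largest 26-connected component. The deliberately strict threshold keeps
   skull-boundary voxels — which belong to no modelled tissue class — out
   of the intensity model; at a looser 0.5 threshold those voxels inflate
   the CSF class variance several-fold and corrupt posteriors near the
   ventricles.
2. **Bias-field correction.** MRI inhomogeneity is modelled as a smooth
   multiplicative field. We fit, by least squares in the log domain, a
   polynomial of total degree `order` (default 3) *jointly* with
   per-tissue intercepts taken from the most probable atlas tissue at each
   voxel. The joint (ANCOVA-style) fit matters: removing tissue means
   first and fitting the polynomial afterwards leaves anatomy-correlated,
   draw-dependent distortions in the field, whereas the joint fit recovers
   a polynomial truth essentially exactly (correlation > 0.99 on
   phantoms). The field is gauge-fixed to mean 1 over the mask, so
   correction preserves global brightness; smoothness is the only property
   assumed of the true field.
3. **Intensity normalization.** Robust anchors: masked median maps to
   1000, masked IQR to 100 (`median_iqr`, the default). The map is
   invertible and equivariant under positive affine intensity transforms;
   combined with the SD-unit threshold below, this makes the final DWMA
   mask invariant to scanner scaling and offset. Per-volume normalization
   is the default; a z-score variant exists. We do not match histograms
   per slice: 3D acquisitions do not require it and it would break the
   affine-equivariance property.
4. **Tissue segmentation.** A three-class Gaussian mixture (CSF/GM/WM)
   with voxelwise atlas priors, fitted by EM: posteriors are proportional
   to prior times Gaussian likelihood; class means and SDs are
   re-estimated from posterior-weighted intensities. Initialization uses
   prior-weighted moments, so the fit is deterministic, and the E-step is
   computed in the log domain so a voxel with an exactly-zero prior for a
   class keeps a zero posterior no matter how extreme its intensity. The
   observed-data log-likelihood is non-decreasing (EM ascent) and is
   checked in the tests at every iteration. `prior_weight` blends the
   atlas prior with a uniform prior (default 1: pure atlas guidance).
   Partial-volume voxels are not given mixture classes of their own; they
   are handled downstream by the 95% membership filter, mirroring the
   published procedure.
5. **Ventricles and centrum semiovale.** Ventricles are the CSF-labelled
   26-connected components majority-covered by the atlas ventricle prior;
   the external CSF rim never qualifies. With `k` the topmost axial slice
   containing a ventricle voxel, the centrum semiovale (CS) is the
   WM-labelled voxels of slices `k+1` and `k+2`, eroded in-plane by one
   voxel (the "central" white matter), minus a ±2-voxel band around the
   mid-sagittal plane. One voxel of erosion and a 2-voxel midline band are
   the defaults; both are configuration-exposed since the anatomical
   definition does not pin them down.
6. **DWMA detection.** Let mu and sigma be the mean and population SD of
   intensity over voxels that are confidently cerebral tissue
   (P(GM) >= 0.95 or P(WM) >= 0.95, pooling both tissues). DWMA candidates
   are CS voxels with intensity strictly greater than mu + alpha x sigma
   *and* P(WM) >= 0.95 — the CS is white matter by definition, while the
   threshold statistics pool GM and WM. The default cut-off alpha = 1.8;
   2.0 is available and is demonstrably more restrictive (fewer voxels on
   every phantom, a property the tests assert). 26-connected components
   smaller than 3 voxels are removed: this automates the manual removal of
   isolated 2-8-voxel false positives, which concentrate in the
   interhemispheric fissure (hence also the midline band).
7. **Volumes.** DWMA volume is exactly voxel volume times voxel count
   (0.8649 mm^3 per voxel at the default 0.93 x 0.93 x 1.0 mm
   resolution). Cerebral WM volume is the posterior-weighted (soft) count
   by default — a hard-count option exists — and normalized DWMA volume is
   their unitless ratio.

## The synthetic-data layer

No imaging data ship with the package; the generator produces phantoms
whose ground truth is known by construction.

**Geometry.** A nested-ellipsoid brain: thin outer CSF rim, cortical GM
ribbon, WM core (radial split at 0.73, giving a cerebral GM:WM volume
ratio near 1:1, in line with term-equivalent morphometry), and two
lateral ventricles interior to the WM core. The ventricles are
superellipsoids (fourth power along z) so their superior surface is blunt
and the "topmost ventricle slice" is crisp — with a pointed top, single
boundary voxels can shift the recovered CS slab by a slice. Optional
seeded jitter (a few percent on the semi-axes) emulates anatomical
variability across subjects. This geometry preserves exactly the
topological facts the pipeline relies on — ventricles inside WM, cortex
outside, WM-rich slices above the ventricles — and nothing else: there is
no cortical folding, no myelination gradient, and no MR physics
simulation.

**Intensities.** Per-tissue Gaussians with T2w ordering CSF (160) > WM
(108) > GM (90) in arbitrary units; the class SDs (5-6) carry the full
within-tissue variability (texture plus thermal noise). A random
full-quadratic multiplicative bias field with peak amplitude 0.2 and a
small additive noise floor (SD 0.5) complete the image model. Gaussian
noise is the default; a Rician option exists, though at structural-T2w
SNR the difference is immaterial for thresholding.

**Lesions.** DWMA lesions are ellipsoids in mm with intensity
WM mean + `offset_sd` x WM SD (default 3). A voxel belongs to a lesion
when its centre lies inside (center-in convention), so truth counts are
integers and `dwma_true_volume_mm3` is exactly voxel volume x count. The
helper `cs_blob()` places a lesion inside the true centrum semiovale:
in-plane extended (default in-plane radius 4.2 mm, about 100 voxels) but
only 1.1 mm in z, because a CS lesion is by definition confined to a
2-slice slab — a sphere of equal volume would span six slices and could
never be recovered from two. The lesion is displaced laterally and
anteriorly away from the column above the ventricles, where smoothed CSF
prior would otherwise depress the WM membership of lesion voxels.

**Cohorts.** Subject tables mirror the structure of a very-preterm
follow-up study: gestational age ~ Normal(28.3, 2.4) weeks, PMA at scan
~ Normal(40.3, 0.5), four centres, a Poisson(2.8) global abnormality
score, and a visual DWMA grade that deliberately carries no signal.
Normalized DWMA volume follows a log-normal with median 0.0073 and
sdlog 1.9 — matching the observed median and upper quartile —
truncated at 0.25, since normalized volumes beyond a quarter of the
white matter are not physically plausible and, at the generating effect
size, would pile subjects onto the Bayley floor and visibly attenuate
any refit. The Bayley Motor composite is linear in normalized DWMA
(-12.59 points per 10-percentage-point increase), gestational age
(+1.28/week) and global score (-0.89/point) with residual SD 9.4,
floored at 40 and capped at 160 (the scale range; untestable children
are conventionally assigned the floor). Cerebral palsy is Bernoulli with
log-odds linear in DWMA (log 31.64 per 10 percentage points, intercept
-3.8, prevalence about 8-11%). The log-normal form is a stand-in: only
the median and IQR of the real distribution are known.

## What the validation shows — and what it cannot

`phantom_recovery_study()` generates ten phantoms (96^3 voxels, default
noise and bias, one CS lesion at +3 WM SD whose in-plane radius varies
2.8-5.4 mm, about 40-160 voxels) and runs the full pipeline. Under these
conditions the pipeline achieves mean Dice >= 0.8 against truth, mean
absolute volume error within 15%, and correlation >= 0.95 between true
and recovered normalized volumes; the lesion sizes are varied precisely
so that this correlation is informative. `cohort_recovery_study()`
refits the generating linear and logistic models on 100 simulated
cohorts of n = 5000 and recovers both DWMA coefficients within 3
standard errors in at least 95% of replicates.

Passing these checks shows the implementation is internally correct and
well-calibrated under the stated image model. It does not show the
pipeline works on real neonatal MRI: the phantoms have piecewise-constant
tissue, spatially independent noise, polynomial bias, and lesions of
known shape, none of which hold exactly in vivo. In particular the
detection operating point is genuinely tight by construction — the lesion
sits 3 within-tissue SDs above WM while the threshold involves the pooled
GM + WM spread — so real-data performance depends on contrast and noise
conditions the phantom only approximates.

## Numerical and convention choices

- Population SD (divisor n) in `cerebral_stats`, for bit-reproducibility;
  at ~10^5 eligible voxels the difference from the sample SD is
  immaterial.
- Strict inequality at the threshold (`> mu + alpha sigma`).
- Hard-label ties resolve in the fixed order CSF < GM < WM.
- EM stops on relative log-likelihood change < 1e-5 or 100 iterations;
  SDs are floored at 1e-6; a class whose posterior mass falls below 10
  voxels raises an error naming the class.
- Non-positive intensities inside the mask are clamped to the smallest
  positive masked value before the log-domain bias fit.
- The 90th-percentile severe-DWMA cut uses linear interpolation between
  order statistics (quantile type 7) and a strict inequality, so ties at
  the cut are not flagged.
- The bootstrap default is the bias-corrected (BC) percentile interval;
  full BCa with jackknife acceleration is an option. Likelihood-ratio
  intervals use the standard log-method SE from the 2x2 counts.
- Internally all volumes are in RAS+ axis order ("above" = increasing
  third index); files are reoriented on load and coordinates are 0-based
  internally, 1-based in logs.
- Whether the WM-volume denominator should be a soft or hard count is not
  determined by the published description; the soft posterior sum is the
  default and a hard count is available (`tissue_volumes(..., hard =
  TRUE)`). On phantoms the two differ by under 2%.

## Problem sizes used in the checks

The shipped tests exercise the full pipeline at 96^3 voxels (ten phantoms
in the acceptance suite, shared fixtures elsewhere), the generators
additionally at 48^3-64^3, and the cohort statistics at n = 5000 with 100
replicates. These sizes were chosen to make every probabilistic check
stable under reseeding while keeping a complete run of the suite on one
CPU comfortable.

## Worked example

```{r, eval = FALSE}
library(neodwma)

atlas <- make_atlas(seed = 1)
lesion <- cs_blob(atlas, radius_mm = 4.2, offset_sd = 3)
spec <- phantom_spec(dwma_blobs = list(lesion), seed = 101)
ph <- make_phantom(spec, atlas)
ph$truth
#> <phantom_truth> 98 DWMA voxels (84.76 mm^3), 100300 WM voxels

out <- run_pipeline(ph$volume, atlas, verbose = TRUE)
out$result
#> <dwma_result>
#>   DWMA voxels:        93 (80.44 mm^3)
#>   cerebral WM volume: 87095.7 mm^3
#>   normalized DWMA:    0.00092
#>   threshold:          1099.453 (mean 997.378 + 1.8 x SD 56.708)
```

The recovered mask overlaps the injected lesion with Dice 0.88 here; a
ten-phantom summary is one call: `phantom_recovery_study(seed = 1)`.

## Known limitations

- The atlas is assumed co-registered; no spatial registration is
  performed or planned.
- The segmentation has no explicit partial-volume or lesion class; very
  large lesions would bias the WM class statistics.
- DWMA is quantified in the centrum semiovale only, by design; the
  periventricular crossroads are excluded rather than modelled.
- The cohort simulator's covariates beyond DWMA, gestational age and
  global score (sex, centre, PMA) carry no generating effect; they exist
  so that model interfaces can be exercised, not to emulate confounding.
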
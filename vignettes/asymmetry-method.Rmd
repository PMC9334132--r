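---
title: "Mirror-asymmetry detection of postictal hyperperfusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-asymmetry detection of postictal hyperperfusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusym)
```

## The detection problem

In poststroke epilepsy, seizure-related hyperperfusion can persist for hours
to days and tends to appear as a focal island of elevated uptake inside the
hypoperfused cortex adjacent to the stroke lesion. Classic subtraction
imaging compares a postictal scan against the patient's own interictal
baseline; `perfusym` implements the single-scan alternative: the brain's
left-right homology is used as the baseline instead. After anatomical
standardization onto a symmetric template, the scan is subtracted from its
own mirror image and the difference is thresholded in SD units.

The central assumption is that, absent pathology, perfusion is
approximately left-right symmetric in standard space, so the mirror
difference is a zero-mean map whose global spread captures both
physiological asymmetry and noise. A *paradoxical asymmetric increase* —
uptake adjacent to a lesion exceeding the homologous contralateral cortex —
then stands out as a positive excursion on the lesion side.

## Pipeline and parameters

`detect_asymmetry()` runs, in order: Gaussian smoothing, automatic stroke
masking, global-mean count normalization, mirror subtraction,
z-standardization, cluster-extent thresholding, anatomical exclusion rules,
and a one-step threshold fallback. All tunables live in `asym_params()`:

| parameter | default | units | role |
|---|---|---|---|
| `smoothing_fwhm_mm` | 10 | mm | isotropic Gaussian FWHM; suppresses count noise and registration residue |
| `stroke_mask_fraction` | 0.30 | – | voxels below this fraction of the whole-brain max form the stroke mask |
| `norm_target` | 100 | – | global mean after count normalization (arbitrary scale; cancels in the z-map) |
| `z_primary` | 2.0 | SD | primary detection threshold |
| `z_fallback` | 1.5 | SD | second pass, only when nothing survives at 2.0 |
| `cluster_extent_min_vox` | 125 | voxels | minimum connected extent; 125 voxels = 1 mL at 2 mm isotropic |
| `max_lesion_distance_mm` | 50 | mm | clusters farther than this from the lesion are artifacts |
| `connectivity` | 26 | – | cluster connectivity (6/18/26); 26 is the common neuroimaging choice |

Two conventions deserve comment:

* **Extent boundary.** "Extent threshold 125" is read inclusively: a
  125-voxel component survives, a 124-voxel one does not. Thresholds of
  this kind conventionally admit the boundary, and 125 voxels is exactly
  1 mL on the 2 mm grid.
* **SD convention.** The z-map divides by the *population* SD of the
  difference map over the inclusion mask (it is the map's own global
  spread, not a sample estimate of something larger); `zscore_map()`
  exposes `sd_type = "sample"` for the n−1 convention.

### Statistics of the mirrored image

The stroke mask must be excluded from the normalization and from the z-map
statistics. For the mirrored image the defect sits at mirrored coordinates,
so the z-map inclusion mask is `brain ∖ (stroke ∪ mirror(stroke))`. Because
the template brain mask is symmetric, the normalization factor of the
mirrored image over the mirrored mask equals the forward factor, so a
single normalization is applied and the difference map is *exactly*
antisymmetric: `D(x) = −D(mirror(x))`. Every positive cluster therefore has
a mirrored negative twin; only the positive side is thresholded, and the
contralateral rule removes the spurious positive twin of any genuine
ipsilateral deficit.

### Exclusion rules and tie-breaking

Clusters are removed when their peak voxel lies outside the template brain
mask or inside the ventricle mask (the reproducible equivalent of visually
discarding extra-cortical and ventricular artifacts); when the minimum
Euclidean distance from any cluster voxel to the nearest lesion voxel
exceeds 50 mm (the most permissive reading of "adjacent"); or when the
cluster centroid lies in the hemisphere opposite the lesion-dominant
hemisphere (the side holding more than half the lesion volume). Clusters
whose centroid is within one voxel of the mid-sagittal plane are never
excluded as contralateral. The reported laterality is the hemisphere of the
maximum-z surviving cluster, ties broken by larger extent, then left before
right — a total order is needed because the verdict reports a single
"maximum change". When the 30 % rule finds no lesion at all, the distance
and contralateral rules are skipped with a warning and the case is flagged.

### Degenerate inputs

A difference map with zero variance over the inclusion mask (e.g. a
noiseless perfectly symmetric scan, or a scan subtracted from itself in the
P−I pipeline) cannot be standardized; the detectors catch this condition
and return a negative verdict with a warning rather than an error, since
"no detectable change" is the scientifically correct reading.

## Registration and standardization

Rigid SPECT-to-MRI co-registration maximizes a 32-bin mutual-information
metric (valid across modalities) over 6 DOF with a three-level
multiresolution schedule (8, 4, 2 mm) and Nelder-Mead. Two numerical
choices matter:

* The optimizer is an in-package Nelder-Mead taking *explicit initial step
  sizes* (degrees and millimetres). `stats::optim` sizes its initial
  simplex from the magnitudes of the starting values, which degenerates for
  warm starts near zero — exactly the situation at every refinement level —
  and stalls at the coarse solution.
* No random sampling is used anywhere, so registration is deterministic;
  on phantoms a 4 mm / 3° perturbation is recovered to about 0.02 mm /
  0.03°.

Anatomical standardization is a deterministic 12-DOF affine estimated by
moment matching: centroids aligned, linear part
`sqrtm(C_template) · sqrtm(C_subject)^{-1}` of the brain-mask covariances.
The same threshold-and-largest-component brain extraction is applied to
both the subject structural and the template reference, making the template
its own exact fixed point. The affine is estimated once per case and the
same parameters standardize every scan of that case. A `pre_aligned` bypass
accepts volumes already on the template grid, so detection behaviour can be
tested independently of registration accuracy. Nonlinear warping is out of
scope; the phantom brains are affine deformations of the template, and real
gyral-level variability would require a proper spatial-normalization tool.

## The synthetic phantom

`make_template()` builds the standard space: a 67 × 81 × 61 grid at 2 mm
(odd left-right dimension, so the mid-sagittal plane is a voxel plane), an
ellipsoidal brain with semi-axes 60 × 75 × 55 mm, a cortical ribbon, a
central ventricle system, and ten geometric sectors named for the lobar
areas (frontal, central, parietal, occipital, temporal × left/right). The
atlas is voxel-exactly flip-symmetric; the sector geometry is a stand-in,
and any conformant label volume (e.g. an AAL-derived merge) can be dropped
in through the same interface.

`simulate_case()` emulates the image structure the method assumes:

* cortex : white matter : CSF uptake at 100 : 60 : 15;
* a spherical stroke lesion (default radius 14 mm) at 10 % of the
  underlying uptake, entirely within one hemisphere;
* a penumbral rim (6 mm shell at 70 %) around it;
* an optional hyperperfusion island adjacent to the lesion (default radius
  8 mm, centre 10 mm beyond the lesion edge, amplitude 0.8 × cortical
  uptake), added to the postictal scan only — or to both scans
  (`chronic = TRUE`) to model a stable asymmetry with no postictal change;
* Poisson count noise: `counts ~ Poisson(intensity × count_scale)` with
  `count_scale = 2`, giving ≈ 7 % voxel noise at cortical uptake —
  variance proportional to the mean, as in real count data;
* a FLAIR-like structural volume delivered on 5 mm slices (exercising the
  resampling step) with a hyperintense lesion;
* optional rigid misalignment of the raw postictal scan.

The island amplitude is a *fraction of cortical uptake*, but the pipeline's
z-scale depends on the whole image (the penumbral asymmetry dominates the
global SD), so `calibrate_island_amplitude()` probes the pipeline itself
and solves for a target peak z by bracketed regula falsi. Peak z is
monotone in amplitude only up to small wiggles (the stroke mask and
normalization both depend on the image maximum), so the calibration accepts
a ±0.05 SD tolerance; the weak-island test targets z ≈ 1.8 with a 17 mm
island so that the suprathreshold extent at 1.5 SD comfortably clears 125
voxels while the peak stays below 2.0.

**What the phantom does not emulate** — and hence what passing tests do not
show about real data: gyral anatomy and true anatomical variability,
scanner point-spread anisotropy, scatter and attenuation artifacts,
physiological (vascular, medication-related) asymmetries of the uptake
pattern, and multi-lesion or bilateral stroke. Detection rates on phantoms
are an upper bound on clinical performance.

## The P−I comparator and its limits

`detect_pi()` mirrors the published comparator: same smoothing, stroke
masking from the postictal scan, joint normalization, z-map over
brain-minus-stroke, 2.0 SD clusters with the same extent rule (exposed as a
parameter, since no extent is stated for this method), hypoperfusion
clusters returned alongside. There is no 1.5 SD fallback and no
distance/contralateral exclusion — those steps belong to the asymmetry
method only.

One structural limitation is worth stating plainly: a self-standardized
z-map of a *pure-noise* difference always has about 2 % of voxels above
2 SD, and 10 mm smoothing makes those excursions form connected clusters
well beyond 125 voxels. An automated P−I verdict with no artifact rejection
is therefore positive for essentially any noisy no-change pair; the
original workflow relied on a human reader discarding scattered blobs. The
package documents this rather than inventing rejection rules the comparator
specification does not contain; the no-change dissociation is exercised
with noiseless pairs, where the difference is identically zero and the
verdict is negative by the degenerate-map rule.

## Problem sizes and determinism

The packaged study conditions were chosen once: Monte-Carlo properties use
20 seeded strong-island phantoms (detection sensitivity and peak-in-island
rate ≥ 90 %) and 20 seeded null phantoms (false-positive rate below 20 %);
the full test suite runs in about three minutes and the acceptance script
in about one. Every stochastic step is seeded: phantoms carry their seed in
the spec, cohorts derive per-case seeds from a master seed, and the
detection and registration paths contain no randomness at all, so identical
inputs give bit-identical results.

## Known limitations

* Affine-only standardization; no gyral atlas (geometric sectors instead).
* The automatic stroke mask can capture any low-uptake region (including
  ventricles); a lesion mask can be supplied to override it.
* The P−I positivity rule is hair-triggered under noise (above).
* Laterality of a midline-peaked detection is reported as `none`.
* The Wilcoxon wrappers inherit `stats::wilcox.test` semantics: exact
  small-sample p-values are unavailable in the presence of ties (the
  normal approximation with tie correction is used instead).
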
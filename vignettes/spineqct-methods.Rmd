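---
title: "Serial quantitative CT of the spine: models, assumptions and validation"
author: "spineqct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial quantitative CT of the spine: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`spineqct` implements a complete longitudinal quantitative-CT (QCT) workflow
for the lumbar spine: phantom-based conversion of attenuation to volumetric
bone mineral density (vBMD), rigid registration of serial scans to the
baseline (preflight) scan, construction and regional partition of the
vertebral trabecular mask, paraspinal muscle cross-sectional area (CSA) and
attenuation-based density, and cohort-level percent-change statistics. The
motivating application is musculoskeletal deconditioning in long-duration
spaceflight crews: three imaging sessions (preflight, postflight, ~12-month
follow-up), 17 subjects with 15 completing follow-up, and missions of 4-7
months. Because no real scans ship with the package, a seeded synthetic
cohort generator with a ground-truth sidecar is a first-class component: it
is the basis of every end-to-end validation claim the package makes.

## The measurement model

**Calibration.** A hydroxyapatite phantom with rods of known density is in
every scan. Each session's calibration is an ordinary least-squares line

$$\rho \;[\mathrm{mg/cm^3}] = a \cdot \mathrm{HU} + b$$

fitted to the rods' mean attenuations (`fit_calibration()`). Rod regions are
eroded in-plane by one voxel before averaging to discard the partial-volume
rim. One calibration per session, never shared: tracking scanner drift is
the phantom's purpose. Because the map is affine, converting a region's mean
HU equals the mean of converted HUs, so region means are converted after
averaging.

**Registration.** Postflight and follow-up scans are registered to the
preflight scan with a 6-degree-of-freedom rigid transform
(`register_rigid()`): intrinsic Z-Y-X Euler angles (degrees) about the fixed
volume's world centre plus a translation in mm, the transform mapping
fixed-space points into moving space. The similarity is the mean squared
intensity difference (the standard mono-modal choice) over a strided sample
of fixed voxels; samples mapping outside the moving field of view compare
against background so that degenerate "everything outside" optima are
penalized. Both images are pre-smoothed with a separable three-point boxcar:
the light low-pass turns aliased binary edges into ramps that trilinear
interpolation represents faithfully, removing the sub-voxel bias those edges
otherwise induce in the MSD optimum. Optimisation is a two-level pyramid
(2x2x1 block-averaged, then full resolution) of BFGS steps using the
analytic metric gradient, initialised at the HU-weighted centre-of-mass
offset and finished with a short Nelder-Mead polish that is insensitive to
the residual kinks of the piecewise-trilinear cost. On the default synthetic
scenes this recovers offsets in the generator's repositioning range (up to
5 mm / 5 degrees) to about 0.2 mm and 0.2 degrees, with or without scanner
noise; non-convergence is flagged on the result, never silent.

**Trabecular mask and regions.** The trabecular mask is the vertebral body
mask eroded in-plane by a cortical margin (default 3 mm) and trimmed axially
by an endplate margin (default 3 mm, rounded up to whole slices)
(`extract_trabecular_mask()`). The mask's axial slices are then assigned
inferior -> transverse -> superior by cumulative fraction (default equal
thirds), with remainder slices landing in the transverse (middle) slab, so
the three regions tile the mask exactly (`partition_regions()`). All masks
are defined once on the preflight scan and mapped into later sessions with
the inverse of the estimated session transform — the matched-ROI design:
sessions are always compared over the same anatomy. Global trabecular vBMD
is the mean over the union of the three regions and therefore exactly their
voxel-count-weighted mean.

Mask mapping uses linear label voting (`resample_label_vote()`): each
label's indicator is interpolated trilinearly and each target voxel takes
the strongest label. On a 1x1x3 mm grid this places mapped boundaries with
sub-voxel accuracy where plain nearest-neighbour rounding can displace them
by up to half a slice — enough to leak endplate signal into the superior and
inferior slabs. Regional means additionally require a winning vote weight of
0.9 (`region_core_weight`), which trims the through-slice partial-volume
band at mapped region boundaries; the regions are internally uniform in the
generator, so restricting to the core is unbiased while removing the
blend-contamination a tilted 3-mm slice profile creates. Plain
nearest-neighbour mapping remains available (`mask_mapping = "nearest"`).

**Muscle morphometry.** The four paraspinal muscles (erector spinae,
transversospinalis, psoas major, quadratus lumborum) are measured on the
single axial slice at the mid-vertebral body — the lower-median slice of the
(mapped) body mask (`select_mid_slice()`). Contours are inputs, not
segmentations: the study's contours were drawn by an operator, and the
generator provides per-session label masks. Voxels outside the closed
window [-50, 150] HU are excluded before anything is computed, removing
pure fat, tendon and bone at the contour periphery; CSA is the retained
count times the in-plane voxel area and density the mean HU of retained
voxels only (`measure_muscle()`). Per muscle, left and right are averaged
for both CSA and density; total CSA is the sum of the four side-averaged
CSAs and total density their CSA-weighted mean (`compute_totals()`). The
side-average-then-sum order is one of two readings of the published
protocol; both orders are trivially recoverable from the per-muscle table.

**Longitudinal statistics.** Flight change is the percent difference of
postflight versus preflight; the monthly rate divides it by the subject's
mission duration (integer months). Readaptation change is follow-up versus
postflight, divided by the elapsed readaptation duration (~12 months) by
default; a `readapt_denominator = "mission"` switch divides by mission
duration instead, as one figure caption literally reads — the default
follows the dimensional sense of "per month of readaptation". Paired t-tests
compare time points (subjects missing a session are dropped pairwise, so
follow-up statistics use 15 of 17 subjects), one-sample t-tests ask whether
monthly rates differ from zero, and ordinary least-squares regressions
relate global vBMD (response) to muscle density and CSA (predictors) within
each session. All tests are two-sided with no multiplicity correction,
mirroring the published analysis; `build_report()` assembles the tables and
flags p <= 0.05.

## What the generator emulates — and what it does not

Each synthetic session is an analytic scene sampled at voxel centres
(default 96x96x40 voxels at 1x1x3 mm):

* **Vertebral body**: an elliptic cylinder (half-axes 22x16 mm, height
  33 mm) with a 2-mm cortical shell, 2-mm endplate slabs and optional
  posterior elements; the trabecular core is split into three axial slabs
  whose boundaries are fixed in preflight scene coordinates, so the
  generator's truth regions coincide with the analysis partition. Default
  preflight regional densities are drawn per subject from the published
  preflight distributions (superior 178.9 +/- 32.4, transverse
  177.5 +/- 29.6, inferior 196.5 +/- 32.4 mg/cm^3).
* **Muscles**: eight elliptic cylinders in an anatomically inspired
  arrangement; voxels are a lean/fat mixture (defaults: lean 55 HU, fat
  -100 HU, lean fraction 0.75). The fat pattern is a deterministic uniform
  field on 1-mm in-plane cells, constant along z — fat streaks run
  longitudinally, move rigidly with the anatomy, and infiltration progresses
  at fixed loci as the lean fraction declines. The baseline lean fraction
  leaves headroom for recovery trajectories drawn from the published
  readaptation distribution without saturating at fully lean muscle.
* **Phantom**: three rods (0/75/150 mg/cm^3 by default — the real phantom's
  rod loadout is not published, so the count and densities are free
  configuration) spanning the full axial field below the body.
* **Scanner**: a true affine HU-density map (default density =
  0.8 HU - 2) inverted to synthesize attenuations; additive Gaussian noise
  (default SD 10 HU); per-session rigid repositioning drawn uniformly within
  +/-5 mm and +/-5 degrees; and a three-point through-slice boxcar that
  mimics a 3-mm slice sensitivity profile, so sub-slice axial shifts change
  boundary voxels the way real thick-slice CT would.

Change trajectories compose multiplicatively on densities, lean fractions
and lean attenuation, and every injected quantity is recorded in the
ground-truth table, where recorded percent changes are exact by
construction. Bone changes can be injected per region either as monthly
rates (applied over the mission or readaptation duration) or as total
percent differences; the defaults are the published flight and readaptation
rate distributions, the mission-duration multiset {4,4,5,5,5,6x7,7x5}
(mean 5.88 months), 17 subjects with the last two lacking follow-up, and
the published muscle CSA and density rate distributions.

The generator deliberately omits trabecular microarchitecture, beam
hardening, metal or motion artifacts, scanner-specific point-spread
behaviour beyond the through-slice boxcar, anatomical variation of shape,
and any bone-muscle correlation in the baselines (regressions on synthetic
cohorts are null-calibrated). Passing end-to-end tests therefore
demonstrates that the measurement chain is unbiased and appropriately
precise for piecewise-uniform anatomy under rigid motion and Gaussian noise
— not that it would segment, register or calibrate clinical scans of real
patients.

## Numerical choices and degenerate inputs

* Erosion is defined on voxel centres: a voxel survives in-plane erosion by
  margin r iff no background centre lies within Euclidean distance r; axial
  trimming removes the smallest whole number of slices covering the margin.
  Margins that consume the whole body are an error that reports the
  remaining voxel count.
* Partition slice counts are floors of the inferior and superior fractions,
  remainder to transverse; a mask spanning fewer than three slices, or a
  region that would receive none, is an error.
* The mid-vertebral slice is the lower median of mask-bearing slices —
  deterministic for even counts.
* A muscle contour whose voxels are all excluded yields CSA 0 with an
  explicit undefined-density flag, not a silent zero.
* Zero-variance inputs to t-tests are errors at the function level; the
  cohort report catches them and reports NA p-values for degenerate metrics
  instead of aborting.
* Registration non-convergence is reported via `converged = FALSE` plus a
  warning; the polish stage counts as converged when it no longer moves the
  descent optimum by more than 0.1 mm / 0.1 degrees.
* All randomness flows from a single cohort seed; regeneration is
  bit-identical, and the disk manifest stores the full configuration plus a
  rolling hash so silent parameter drift is detectable.

## Validation design and problem sizes

The test suite freezes hand-computable oracles (closed-form least squares
and t statistics, brute-force erosion, exhaustive voxel counts) and checks
the exact structural identities: partition conservation, the
global-equals-weighted-regional identity, window idempotence for muscle
metrics, and the calibration round trip (<= 1e-6 relative error at zero
noise). Printed monthly-rate p-values (0.0012, 0.0015, 0.079) are recomputed
from their summary triples via deterministic mean/SD-matched samples; since
the published means and SDs are themselves rounded to two decimals,
agreement is to about one unit in the last printed digit.

End-to-end recovery uses full synthetic cohorts at the study's design size
(17 subjects, follow-up for 15, 96x96x40 voxels). The acceptance script
averages five seeds; the in-suite recovery blocks average three (two for the
three-session design) to keep the default test run desk-scale — with
mean/SD-matched draws the injected cohort moments are exact in every seed,
so seed averaging only damps residual measurement noise. Cohort draws use
`rnorm_cohort(..., empirical = TRUE)` in these experiments precisely so that
the recovery error isolates the measurement chain rather than finite-sample
wobble of the injected effects; the generator's default remains plain
i.i.d. sampling.

Known residual effects, all small against the published between-subject
SDs: single-slice CSA carries ~2% per-subject sampling noise when a rotated
session resamples the fat-streak field (cohort means are unaffected to
within ~0.1 %/month); muscle density carries a sub-percent partial-volume
rim effect; and mapped-mask regional means would inherit slice-boundary
blends without the 0.9 core-weight trim.

## Limitations

The pipeline measures; it does not segment. Vertebral body and muscle
contours must be supplied (by the generator or a user), matching a study
design in which delineation was manual. Rigid registration assumes the
vertebra moves as a rigid body between sessions — adequate for a single
vertebral level, wrong across levels or for deformable anatomy. The
linear calibration is specific to in-scan phantoms; asynchronous or
phantomless calibration is out of scope. Nonlinear time courses of bone
loss and recovery are not modelled: rates are straight-line summaries
between two time points, as in the source analysis.
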
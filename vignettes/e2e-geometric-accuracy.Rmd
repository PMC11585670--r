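---
title: "Measuring end-to-end geometric accuracy of MR-linac dose delivery"
author: "e2edose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring end-to-end geometric accuracy of MR-linac dose delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e2edose)
```

## The problem

An end-to-end (E2E) test of an MR-linac exercises the whole online adaptive
treatment chain — imaging, registration, plan adaptation, and delivery — and
asks a single question: *was the dose delivered at the right place?* A 3D
dosimeter (a polymer gel in a head phantom) records the delivered dose
volumetrically; 2D radiochromic film serves as the established reference.
The residual rigid displacement between the planned dose distribution and
the dosimeter's readout, recovered by image registration, is the geometric
error of the chain; its spread over repeated measurement sessions is the
reproducibility. A gamma analysis of the same pair quantifies dosimetric
agreement.

Real E2E measurements require a linac, a phantom, and dosimeter logistics.
This package reproduces the *analysis* chain on simulated measurements with
known ground truth, so every stage — dosimeter models, the registration
estimator, the gamma engine, and the session statistics — is testable
against exact expectations. The same functions accept imported volumetric
data (NIfTI), so the pipeline applies unchanged to real readouts.

## The phantom plan model

The test plan irradiates two identical truncated cones (planning target
volumes, PTVs), mirrored in the longitudinal direction `z` about the plane
`z = 0`, with tip diameter 0.5 cm, base diameter 3.0 cm and length 4.6 cm.
The cone geometry makes every rigid displacement visible: a shift along the
cone axis changes the cross-section diameter, so even the direction
orthogonal to a 2D film plane leaves a measurable signature. The prescribed
maximum dose in the PTVs is 11 Gy with dose outside the PTVs capped at
6 Gy. All coordinates are in the IEC 61217 patient frame (x lateral,
y vertical, z longitudinal) in mm; dose is in Gy.

`generate_plan_dose()` builds the dose as a background plateau over the
head region plus the two cone indicator fields, blurred by an isotropic
Gaussian penumbra (`penumbra_sigma`, default 3 mm — the scale of an
MR-linac beam penumbra), optional per-voxel Gaussian noise, and an exact
rescaling so `max(dose over PTV voxels) == ptv_max_dose`. This is a
geometric stand-in for a treatment-planning-system dose: the registration
and gamma procedures need realistic dose gradients, not a beam model.
Deliberately **not** modelled: the 13-beam IMRT segment structure,
anthropomorphic heterogeneities (skull, cavities), electron densities, and
the online plan re-optimisation itself. Passing tests therefore demonstrate
the correctness of the *analysis* under controlled conditions, not the
performance of any physical machine.

Two lattice presets mirror the study resolutions: `"recalculated"` (1.0 mm
isotropic, 120 × 120 × 160 voxels, default noise 0.1% of the maximum — the
statistical level of an offline recalculated plan) and `"online"` (3.0 mm
isotropic). Cone axes run along y with apexes separated in z; positions are
configurable since only the mirror symmetry is structurally required.

## Dosimeter chains

**Gel.** Polymer gel dosimeters respond to dose with an increase of the MRI
transverse relaxation rate R2 (s⁻¹), linear up to about 20 Gy.
`simulate_gel()` resamples the dose onto the gel MRI lattice (default
0.78 × 0.78 × 2.0 mm) and applies `R2 = a + b · D` plus Gaussian noise;
defaults `a = 1.2` s⁻¹, `b = 0.4` s⁻¹/Gy are typical of VIPAR-class gels
read at 1.5 T. `fit_r2_from_echoes()` recovers R2 from multi-echo
magnitudes by per-voxel log-linear least squares (exact on noiseless
mono-exponential decays). `gel_to_dose()` inverts the chain: subtract the
baseline, resample to an isotropic 1.0 mm output lattice, and rescale so
the readout maximum equals the maximum calculated dose. The rescaling is
applied *after* resampling, as division by the observed maximum followed by
multiplication with the reference, so the output maximum equals the
reference exactly (a normalisation the tests assert with
`expect_identical`). Negative values are clipped to zero.

**Film.** Radiochromic film darkens with dose; the net optical density
(netOD) converts to dose through a session-specific calibration curve.
The curve is parameterised as `D = b·netOD + c·netOD^n` with fixed
`n = 2.5` — the standard radiochromic form with no constant term, strictly
monotone over the working range, fitted linearly in `(netOD, netOD^n)` from
at least four known dose levels. Scanner physics (RGB channels, lateral
response, flat-fielding) is abstracted to the single netOD channel; OD
noise and marker jitter are the configurable error sources. The film is
registered into the 3D frame by point-matching the circular cut-out centres
against MR-visible markers with the closed-form orthogonal-Procrustes
(Kabsch) solution; collinearity is rejected at a 1e-6 tolerance on the
second singular value of the centred source points.

`place_film_in_3d()` returns a `film_placement` — pixel values plus their
exact transformed world coordinates and an in-plane validity mask — rather
than forcing the (possibly rotated) plane onto an axis-aligned lattice.
The registration fit and the film gamma consume it like a one-voxel-thick
grid. This was a genuine design fork: an axis-aligned single-slice
`dose_grid` would be simpler but cannot represent a marker registration
with a non-trivial rotation without an extra interpolation; carrying exact
coordinates keeps the marker-registration error chain free of resampling
artefacts.

## The registration estimator

The geometric error is the translation `t` maximising the correlation
ratio between the measured readout and the planned dose resampled at
`x − t`, over a region of interest (ROI) encapsulating both PTVs (cone
bounding boxes plus a 5 mm margin). The correlation ratio
η²(fixed | moving) = 1 − E[Var(fixed | moving bin)] / Var(fixed)
is 1 under any deterministic intensity relationship and is invariant under
affine rescaling of either image — exactly the robustness needed when the
readout is a linearly converted, renormalised R2 map. The measured dose is
the dependent image; the resampled planned dose defines the bins (64
equal-width bins over the masked range; empty bins contribute nothing).

The optimiser is the classic Hooke–Jeeves pattern search: exploratory
± step moves per axis in fixed order (positive first, strict improvement
required), pattern moves that double a successful displacement, and
geometric step reduction (factor 0.5) on failure. Defaults: initial step
2.0 mm, minimum step 0.01 mm, at most 200 iterations, ± 10 mm bounds. The
0.01 mm resolution sits two orders of magnitude below the sub-millimetre
effects of interest; the search is fully deterministic, and candidate
shifts for which less than half the ROI maps inside the planned grid are
rejected. Only translations are fitted (3 degrees of freedom): rotations
are not part of the reported E2E quantities, and the dual-cone geometry
gives translation the dominant signature. For film, the same 3-DOF fit runs
on the plane's sample points; out-of-plane sensitivity comes only from the
cone taper and is intrinsically weak — the expected behaviour for a 2D
dosimeter, and the reason the 3D gel is interesting. A `free_axes` switch
provides the in-plane 2-DOF variant.

Shift reporting follows the convention that the returned vector maps the
planned dose onto the measurement. Per-axis shifts are summarised as planar
root-sum-square vectors in all three coordinate planes (`v_xy`, `v_xz`,
`v_yz`) plus the 3D vector; under IEC 61217 a coronal film plane spans x–z
and a sagittal plane y–z, and labelling all three projections explicitly
avoids any ambiguity about which plane a "2D vector" refers to. Session
reproducibility is the sample standard deviation (n − 1) over a session's
measurements.

## Gamma analysis

`gamma_map()` implements the global gamma index: for every reference voxel
at or above 20% of the maximum planned dose,

γ(r) = min over p of sqrt( (‖p − r‖/Δd)² + ((D_eval(p) − D_ref(r))/ΔD)² )

with Δd = 3 mm, ΔD = 3% of the maximum planned dose, candidates `p` on a
sub-grid of step 0.1 · Δd (0.3 mm) within 2 · Δd of the voxel, sampled
trilinearly from the evaluated grid. The sub-grid step bounds the
discretisation error at roughly 0.005 in γ; voxels below threshold, or
with no valid candidate, are excluded from the pass rate. γ ≤ 1 passes,
with a 1e-9 boundary tolerance so closed-form cases that land exactly on
the criterion are not flipped by floating-point representation. The
optimised engine visits candidates sorted by distance and stops when the
distance term alone reaches the running minimum — a provably lossless cut,
verified voxel-for-voxel against `gamma_brute_force()` (the same
definition, exhaustively evaluated) and, on small grids, against an
independent pure-R implementation in the test suite. In the pipeline the
gamma runs on the *registered but unfitted* pair, so residual geometric
error remains visible in the dosimetric comparison; film gamma runs the
same engine on the film plane with candidates confined to it.

## Numerical choices and degenerate inputs

* Voxel convention: `origin` is the centre of the first voxel; trilinear
  interpolation is exact at voxel centres and on globally linear fields;
  points outside the voxel-centre hull are flagged, never extrapolated.
  Validity masks propagate through resampling and are excluded from the
  correlation ratio and gamma — zero-filling would bias both.
* Interpolation is trilinear throughout, for determinism and speed. A
  consequence worth knowing: resampling twice (t₁ then t₂) equals
  resampling once by the composition only up to second-order interpolation
  error on curved fields; the tests assert exact composition on linear
  fields and an interpolation-level bound on smooth ones.
* Exact normalisations (`PTV max = 11 Gy`, gel output max = reference max)
  are implemented as divide-by-observed-maximum then multiply-by-target, so
  the extremal voxel maps to the target bit-exactly.
* Degenerate inputs fail loudly: constant fixed intensities (undefined
  correlation ratio), constant R2 maps (zero dynamic range), collinear
  markers, empty ROIs, reference grids with no voxel above threshold.
* All randomness flows from explicit integer seeds; identical configs and
  seeds give byte-identical session reports (asserted in the tests by
  serialising twice).

## Problem sizes in the test suite

Unit tests run on a compact 64 × 72 × 96 plan with the same cone geometry;
the acceptance-style tests run the native 1 mm study lattice
(120 × 120 × 160) for shift recovery (10 noiseless trials, 10 noisy gel
seeds, 100 jittered film trials), gamma oracle equivalence on ten 20³
random smooth pairs, and a five-measurement end-to-end gel session. These
sizes keep a full run in minutes while exercising every code path at study
resolution.

## Limitations

* Axis-aligned grids only; oblique acquisition geometries must be resampled
  upstream. Volumetric I/O is NIfTI; DICOM RT Dose import is out of scope.
* The dose model is geometric; findings about estimator accuracy transfer
  to real TPS doses only insofar as those share smooth, high-gradient
  structure around the targets.
* Gel and film physics are reduced to their dose-response laws plus
  Gaussian noise: no B0/B1 inhomogeneity, temporal drift, scanner lateral
  response, or water-gap effects. The vendor-side registration of the
  post-delivery MRI to the online MRI is assumed done; residual
  misregistration is representable as part of the ground-truth shift.
* Rotational delivery errors are simulated (`rigid_transform` supports
  rotations) but not fitted.
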
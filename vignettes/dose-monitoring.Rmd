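---
title: "CBCT-based synthetic CTs and D99 triggers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CBCT-based synthetic CTs and D99 triggers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models, their
assumptions, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open. No empirical claims are
made here beyond what the test-suite and `scripts/acceptance.R` themselves
compute.

## 1. Why synthetic CTs

Proton dose deposition is governed by the stopping-power ratio (SPR) along
each beam, obtained from CT numbers through a calibration curve. Cone-beam
CT acquired at the treatment position has uncalibrated, spatially drifting
gray values — scatter, beam hardening and photon starvation produce both a
global monotone distortion of the intensity scale and smooth low-frequency
shading — so dose cannot be recomputed on it directly. The package builds
three CT-valued images per monitoring event:

* **corrCBCT**: keep the CBCT's geometry (it shows the true treatment-day
  anatomy and setup) and repair its intensities;
* **virtCT**: keep the planning CT's calibrated intensities (deformed to
  the CBCT) and repair its low-density anatomy;
* **gtCT**: deform a same-day verification CT to the CBCT — the reference
  against which the two surrogates are scored.

## 2. Image model and geometry

Volumes are axis-aligned scalar grids with per-axis spacing in mm
(X right-left, Y anterior-posterior, Z inferior-superior), 0-based voxel
indexing with `position = origin + index * spacing`. Grid presets follow
the clinical acquisition geometry (CBCT 512x512x110 at 0.54/0.54/2.50 mm
with a 26 cm field of view; CT 512x512x387 at 1.17/1.17/1.00 mm). The
test-suite and the examples run on a downscaled preset (96x64x56 at
~4 mm) covering the same physical head/neck/shoulder extent; this is a
deliberate package choice so that a complete pipeline run is interactive,
and every algorithmic parameter is expressed in physical units so results
transfer across presets. CBCT gray values are kept unscaled (`CBCT_GRAY`)
and never silently treated as HU; out-of-extent resampling pads CT-class
images with -1000 HU, the physical air surround.

Morphological operations (field-of-view retraction, feathering, signed
distance) use an exact squared Euclidean distance transform computed by
separable min-convolution in physical units, so the 2.5 mm slice direction
is handled correctly; erosion by a ball is distance-transform thresholding,
not iterated structuring elements.

## 3. The phantom simulator

The generator's job is to carry the statistical structure the algorithms
assume, not anatomical realism. It emulates: three separable tissue classes
(air ~ -1000 HU, soft tissue ~ 40 HU with a smooth 25-HU heterogeneity
field of ~10 mm correlation length, bone ~ 700 HU) on a head/neck/shoulder
body; spine, mandible and shoulder bone surrogates; pharyngeal and nasal
air cavities; a spherical high-risk CTV in the mid neck and an elongated
standard-risk CTV following the nodal chain inferiorly toward the
shoulders. Anatomical change is applied as an *analytic pull-back
deformation* — exact local scaling about the high-risk target (default
shrink fraction 0.164, the reported mean early-course GTV volume
reduction) and exact local translation of the shoulder surrogates, each
with a smooth cosine taper to identity — so the ground-truth field is known
in closed form for registration scoring. Air-cavity filling is an intensity
change, deliberately invisible to the deformation ground truth.

CBCT degradation is applied **in image space**: `gray = g(HU) + shading +
streaks + noise` with `g` a strictly monotone gain/offset (default
0.8 / 40) plus optional mild quadratic term; shading is a long-wavelength
cosine field (default amplitude 60 gray units in the cohort scenario;
wavelength 400 mm, i.e. a cupping-like bowl across the whole field of
view — "low-frequency" made operational); shoulder streaks are a localized
negative bias between the shoulder surrogates; the field of view is a
260 mm cylinder. Projection-domain physics (scatter kernels,
reconstruction) is not simulated: the correction algorithms only ever see
image-domain data, and reconstruction-parameter variations were reported
not to matter for the downstream dose. Consequences: passing tests show
the algorithms recover *systematic, low-frequency, monotone* corruptions;
they say nothing about streak-rich projection artifacts beyond the
qualitative shoulder-streak scenario, nor about real tissue-class overlap
(fat is not modelled as a separate class).

## 4. Registration

Rigid alignment minimizes overlap-region mean squared difference
(Nelder-Mead over translation + small rotations, exhaustive +-12 mm coarse
translation search first — the similarity landscape at coarse resolution
is too flat and rugged for a simplex started at zero). The deformable step
is a multi-resolution demons-style method: force
`-(m_w - f) grad f / (|grad f|^2 + (m_w - f)^2 / s^2)` with per-iteration
Gaussian fluid smoothing (sigma 8 mm) of the update and diffusion
smoothing (sigma 3.5 mm) of the field, displacement step capped at 2 mm,
fixed iteration schedules (60/40/12 at downsampling 4/2/1) with an early
stop when the focus-region MSE plateaus. The commercial hybrid algorithm
the clinical workflow uses is explicitly not replicated; only its
contract is: a plausible smooth field, restricted to a focus region, with
scripted contour mapping.

The ground-truth CT pipeline rigidly aligns the verification CT to the
(converted, artifact-corrected) CBCT before the deformable step: bulk
setup differences are rigid, and the zero-outside-focus contract makes a
global translation inexpressible as a pure deformable field. The rigid
and deformable transforms are composed into one pull-back field so image
warping and contour mapping share a single total transform.

Two contract details are enforced exactly rather than approximately:
displacements are *identically zero* outside the focus region (the CBCT
FOV retracted 20 mm, to keep the optimization away from FOV edge
effects), and the same focus rule is applied to the vfCT-to-CBCT
registration that builds the gtCT — the source text is silent there, and
using one rule for all three images keeps the surrogates commensurate.
Convergence is judged within the finest level only (MSE scales differ
across resolutions); divergence raises an error carrying the iteration
trace. Inverse consistency is reported via a fixed-point numerical
inverse.

Contours are mapped by warping each mask's *signed distance function* and
thresholding at zero rather than interpolating the 0/1 indicator: at
4 mm voxels an indicator threshold quantizes boundary motion to half a
voxel and a planted 16.4% volume change simply vanishes; the signed
distance tracks sub-voxel boundary motion. This is the one place the
implementation deviates from the obvious partial-volume rule, and it is a
strict improvement at coarse voxelization.

## 5. The corrected CBCT

Per iteration: deformable registration of the pCT to the (currently
converted) CBCT inside the focus region; joint histogram (96x96 bins over
the in-focus intensity ranges); tissue-class identification on the
smoothed gray marginal — modes are accepted highest-first only if a
genuine valley (below 60% of the candidate's height) separates them from
every accepted mode, and each junction is estimated from a tight +-3-bin
window around its mode so junctions sit *on* the true gray-to-HU curve
rather than being dragged by partial-volume tails; piecewise-linear
conversion through the junctions (terminal-slope extrapolation, clamped to
[-1024, 3071] HU, isotonic adjustment with a warning if HU ordering ever
breaks); then artifact correction: the low-pass-filtered difference
between converted CBCT and deformed pCT is subtracted. The low-pass is a
Gaussian with sigma 15 mm in physical units, mask-normalized so air
outside the body does not bleed in and feathered to zero over 10 mm at
the mask edge. The sigma default deserves a note: cupping-style shading
varies over the whole field of view (wavelength hundreds of mm), and a
25 mm sigma measurably under-recovers it (a ~6 HU mean soft-tissue
residual survives even with perfect registration on the shipped phantoms)
while 15 mm leaves ~2.5 HU and still attenuates 1-voxel impulses by three
orders of magnitude; 15 mm is therefore the default, and the constant is
configurable. The difference map is robustified in two passes: voxels
with |difference| above 200 HU (filled cavities, misregistered bone —
genuine anatomy change, not artifact) are excluded outright, and voxels
deviating by more than 100 HU from the first-pass low-frequency field are
excluded from a second, final pass. Within the iteration loop the image
is converted and artifact-corrected *before* each registration, so
shading never masquerades as deformation. The loop stops when the
corrected image changes by less than 2 HU mean absolute difference
(default cap 5 iterations); re-registrations after the first pass are
warm-started with reduced schedules, which reaches the same fixed point at
a fraction of the cost. The artifact map is applied in HU space after
conversion (the alternative — gray space before conversion — is equivalent
to first order since the conversion is piecewise linear; HU space keeps
the map in the units of its consumers). Class count defaults to 4 (air, a
fat/soft-tissue boundary, soft tissue, bone); with strong class overlap
fewer junctions survive the valley criterion, which degrades gracefully
toward a two-point (air/soft) calibration.

The composite output equals the corrected CBCT deep inside the FOV, the
deformed pCT outside it, with a 10 mm linear feather *inside* the FOV
boundary; voxels outside the FOV are bit-identical to the deformed pCT.

## 6. The virtual CT and the masking rule

`virtCT = warp(pCT)`, except voxels inside the FOV where
`|rho_virt - rho_corr| > 0.3 g/cm3` *and* `min(rho_virt, rho_corr) <
0.6 g/cm3`, which take the corrCBCT CT number. Both inequalities are
strict, exactly as printed — a difference of exactly 0.3 or a density of
exactly 0.6 does not override. Both densities come from the same
calibration (air -1000 HU -> 0.001, water 0 -> 1.0, bone 1500 -> 1.85
g/cm3, terminal-slope extension, floored at 1e-4), so the comparison is
commensurate. The shoulder-streak scenario reproduces the known failure
mode: streak-depressed corrCBCT values masquerade as low density and leak
into the virtCT between the shoulders; the test-suite asserts the spurious
override count decreases monotonically to zero as the planted streak
amplitude goes to zero.

## 7. Dose proxy, DVH, triggers

The dose engine is an explicit simplification, designed so that *relative
D99 change between image sets* — the quantity the trigger consumes — is
driven by the same mechanism as in a real proton calculation: range shifts
from density errors. HU maps to SPR through anchors (-1000 -> 0.001,
0 -> 1.0, 1500 -> 1.55). Per beam (presets: one anterior plus two
posterior-oblique beams at +-45 degrees with weights 0.4/0.3/0.3, the
posterior-dominant mirror, or a single beam), the SPR volume is resampled
into a beam-aligned frame and water-equivalent depth accumulated along the
beam axis — mathematically the per-voxel WEPL line integral, computed as a
cumulative sum at depth steps of half the minimum voxel spacing. The
per-ray planned range is the WEPL of the distal target edge plus a 4 mm
margin, planned on the *planning* SPR; the aperture is the target's beam's-eye
projection dilated by 6 mm. The depth dose is a flat plateau to the
planned range with a linear distal falloff over 5 mm WEPL; no lateral
scatter, no nuclear halo, no robustness evaluation. Doses are normalized
so the planning geometry yields D99(high-risk CTV) = 100; D99 is the
`ceiling(0.99 n)`-th largest in-mask dose (the lower-quantile convention;
the DVH itself is exact counting, no interpolation). At the clinical
preset the dose grid would be 2x2x2 mm; at the downscaled preset doses
are computed on the image grid.

Trigger rule: `delta D99 = D99_plan - D99_eval` in percentage points of
plan-normalized relative dose (positive = loss); review when
`> 3` (high-risk) or `> 5` (standard-risk), strict, with boundary hits
logged. The "percentage points of relative dose" reading of the thresholds
is a documented choice — relative-relative percentages would differ only
in the second decimal at these magnitudes.

Cohort statistics: per surrogate and structure, mean +- SD of |delta D99|
against the gtCT; paired two-sided Wilcoxon signed-rank tests (zeros
dropped per Wilcoxon's convention, midranks for ties; exact
generating-function enumeration for n <= 15, tie-corrected normal
approximation with continuity correction above; significance at p < 0.05)
for all three surrogate pairings; quartiles of gtCT coverage loss; review
counts. The 84-patient cohort values from the source study are not
reproducible from synthetic data and are not targeted; the planted-cohort
tests instead verify the estimators (means within sampling error, trigger
counts exactly matching the plant list, consistency of the review-rate
estimator at n = 50/200/800).

## 8. Numerical choices and degenerate inputs

* Gaussian filtering is FFT-based with physical-units sigma; the artifact
  map pads by 3 sigma to avoid wrap-around, field smoothing inside demons
  does not (fields are small near the grid edge and the focus mask re-zeros
  them).
* The distance transform truncates its per-axis search at the query radius
  plus one voxel: thresholded results are exact, full transforms are exact
  up to the cap.
* Empty focus regions, empty masks, all-zero Wilcoxon differences,
  non-monotone calibrations and gray maps, sub-2-mode histograms, and
  missing case files all raise early, named errors rather than propagating
  NaNs.
* All randomness (phantom texture, noise, cohort draws) flows from
  explicit integer seeds; registration and dose are deterministic given
  inputs, so every artifact is reproducible from the manifest.

## 9. Problem sizes

The shipped tests and the acceptance script run at the downscaled preset
(96x64x56 voxels at ~4 mm; one fine-grid 2.5 mm run for the sub-voxel
volume-ratio check; 200 planted cohort cases; 50-400-voxel DVH oracles).
These sizes were chosen so a full suite run stays in the tens of minutes
on a single CPU while every property remains measurable at its stated
tolerance.

## 10. Known limitations

* The dose proxy's absolute D99 losses can exceed clinically reported
  magnitudes (no lateral scatter smearing the distal edge); only relative
  comparisons across image sets are meaningful.
* Tissue classes are well separated by construction; heavily overlapping
  class histograms would exercise the degenerate-histogram fallback path
  more than the shipped phantoms do.
* The demons registration satisfies the stated recovery contracts on
  smooth planted fields; sliding interfaces and topology change (real
  tumor regression) are outside its model class.
* MetaImage IO is not implemented; NIfTI is the package's interchange
  format.
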
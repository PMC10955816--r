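---
title: "Simulating a multisource cone-beam CT scanner: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a multisource cone-beam CT scanner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mscbct)
```

## The scanner being modelled

Conventional cone-beam CT (CBCT) acquires a whole volume in one gantry
rotation with a single wide-cone X-ray beam.  The wide cone is also the
source of CBCT's main weaknesses: the large irradiated volume generates
strong object scatter (depressing soft-tissue contrast and biasing
Hounsfield units, most visibly as the cupping artefact), and the large cone
angle under-samples off-centre axial planes (the classic disc-stack, or
Defrise, artefact) and truncates the usable axial coverage.

The multisource design replaces the single tube with an axial array of
eight focal spots at 12 mm pitch, each collimated to a thin axial slab
(32.5 mm full width at half maximum at the detector, about a 3 degree
cone) that exposes the full detector width.  The sources fire sequentially
at every gantry position, so a scan collects `nViews * nSources` narrow
frames instead of `nViews` wide ones.  A flat panel (147.3 x 113.7 mm,
0.198 mm binned pixels) is shifted laterally by 70 mm so that over a full
rotation the offset halves cover a 187 mm transaxial field of view.  The
same scanner operated with one source and the collimation opened to the
full panel height ("N1", `n1Degenerate()`) is the internal wide-cone
baseline: same detector, same dose-rate, same reconstruction.

`mscbct` implements this system end to end in simulation: geometry and
dose arithmetic, voxel phantoms, an exact ray-driven projector, a
surrogate scatter model with the adjacent scatter ratio subtraction (ASRS)
correction, a single-system-matrix SIRT reconstruction with optional
total-variation (TV) denoising, Hounsfield calibration, and the CT quality
metrics used to compare the two configurations.

## Geometry

All lengths are millimetres.  The source-to-detector distance is 615 mm.
The source-to-isocenter distance is not a published quantity; the
constructor derives it from the requested transaxial field of view: the
offset panel's far edge, scaled to the isocenter, must reach the FOV
radius, `(offset + width/2) * SID/SDD = 93.5`, giving SID close to 400 mm.
It can be overridden in `buildGeometry()`.

Each source's beam is centred on the axial plane containing that source
(the simplest layout consistent with a common collimator), so the
illuminated detector band of source *s* is centred on that source's axial
position.  The printed beam FWHM (32.5 mm at the detector) and the printed
cone angle (2.4 degrees) are mutually inconsistent by roughly 25%; the
FWHM drives all collimation masks, and the angle is reported only as
derived metadata (`coneHalfAngle()`).  The eight slabs overlap at the
isocenter (7.8 mm source pitch at isocenter scale against a 21 mm slab),
so the union covers a contiguous ~105 mm axial interval; the wide-cone
baseline covers ~74 mm.

Views are `nViews` evenly spaced gantry angles over 360 degrees, all
sources firing at the same angle (step-and-shoot).  Whether the physical
scanner drifts in angle across the eight firings of one view is not
documented; the step-and-shoot approximation keeps the system matrix
identical for both configurations, which is the property that matters for
the comparisons made here.

## Dose and timing arithmetic

Scan time is `(tReadout + tExposure) * nViews * nSources`; with the
11.6 ms readout, 6.5 ms pulses, 360 views and 8 sources this is 52 s.  The
dose-area product is `doseRate * tExposure * area * nViews * nSources`
with `area = detWidth * beamFwhm` (the panel area illuminated per pulse);
with the measured 1299 uGy/s it evaluates to 11.6 dGy cm^2, matching the
published 11.8 dGy cm^2 within the rounding of the printed inputs.
Per-source tube load is `current * tExposure * nViews` (35.1 mAs).  The
conversion from DAP to dose at the rotation centre is scanner-specific and
is exposed only as a user-supplied factor in `doseReport()`.

## Phantoms

`makeDefrise()` builds the disc stack (160 mm diameter, 4 mm acrylic discs
with 4 mm gaps; 12 discs by default, sized to fill the multisource axial
coverage).  `makeContrast()` builds the 160 mm water-equivalent cylinder;
its four 25 mm wells (acrylic +120 HU, LDPE -95 HU, air -1000 HU, and a
machinable glass ceramic) sit at 45 mm radius, 90 degrees apart --
the wells' positions and diameters are not published and these are package
conventions.  The ceramic has no standard nominal value at 90 kVp; its
default (2400 HU) is a convention chosen near diagnostic-CT readings and
is configurable.  `makeHead()` is a deliberately synthetic stand-in for an
anthropomorphic head (elliptical soft tissue, a mandible-like arc with a
cortical shell around a cancellous core, teeth-like cylinders sharing the
cortical material class) intended for threshold segmentation and
slice-wise agreement statistics, not anatomical realism.

Attenuation is monoenergetic: `mu = muWater * (1 + HU/1000)` with
`muWater = 0.02` per mm (an effective energy plausible for a 90 kVp beam).
This keeps truth exact and makes Hounsfield calibration linear; beam
hardening is deliberately out of scope.  Phantoms are rasterized at twice
the voxel resolution: boundary voxels get fractional attenuation (the mean
over subvoxels) and the majority material label, so projector oracles
against analytic volumes and areas hold to ~1-2% at desk-scale voxels.

## Projector and noise

The forward model traces one ray per pixel centre with exact ray/voxel
intersection lengths (Siddon-style incremental traversal, implemented in
C++).  The forward and adjoint operators share the single traversal
routine, so the pair is matched to floating-point precision -- the inner
product identity holds to ~1e-12 and is asserted at 1e-4 in the tests.
The detector is an ideal photon counter (no blur, gain or lag): the claims
under test are geometric and scatter-driven, and detector physics would
only blur the comparison.

Collimation multiplies intensities by a per-row transmission profile: 1
inside the FWHM band, a Gaussian penumbra (sigma 1 mm at the detector, a
convention -- the physical penumbra shape is not documented) outside it,
cut to zero below 5% transmission.  Expected intensity is
`i0 * mask * exp(-p)`; with a finite photon budget every pixel is
Poisson-sampled from a per-frame stream derived from the top-level seed,
making scans bit-reproducible.

Reconstruction consumes only the umbra rows (mask exactly 1).  This is a
deliberate choice, made after observing a reconstruction artefact rather
than before: if penumbra rows are log-normalized by their small incident
intensity, any residual scatter in them is amplified by the inverse mask,
and because every view's inner panel edge maps to the rotation axis these
errors accumulate into a seam at the centre of the volume.  Discarding
rows with less than full beam transmission is standard practice and
removes the artefact; the slabs still overlap axially, so no coverage is
lost.

## The surrogate scatter model

Physical scatter transport is out of scope; the model is a declared
surrogate whose job is to reproduce the phenomenology that the multisource
design and the ASRS correction respond to:

* the scatter field of a frame is a very broad Gaussian blur (sigma
  300 mm, quasi-flat across the 147 mm panel) of that frame's primary
  intensity, renormalized per pixel so the field does not fall off at the
  panel edges -- the panel samples the interior of a much wider
  distribution;
* the field is rescaled per frame so the mean in-band scatter-to-primary
  ratio (SPR) equals `amplitude * bandWidth / referenceWidth`.  In-band
  SPR therefore grows proportionally with the axial beam width, which is
  the physical mechanism that makes the wide cone scatter-rich (SPR ~1
  for the full-height beam over a 16 cm water cylinder, a typical
  uncorrected CBCT value) and the collimated beams scatter-poor
  (SPR ~0.29, the band-width ratio).

Two properties of this construction matter.  First, the SPR ratio between
the configurations equals the band-width ratio by construction, so the
scatter *reduction* attributable to collimation is modelled exactly rather
than emergent from an uncontrolled kernel.  A naive formulation that
multiplies a band-width prefactor onto an energy-preserving blur would
count the band width twice (the blur already dilutes a narrow band's
scatter) and cannot simultaneously keep the SPR ratio near the band ratio
and leave enough scatter outside the band for adjacent-row sampling; the
per-frame rescaling resolves that tension and is the reason the model is
stated this way.  Second, the kernel width controls the artefact the
uncorrected reconstruction exhibits: a quasi-flat field (sigma large
against the panel) reproduces the classic cupping depression at the object
centre, whereas a kernel narrow enough to follow the object shadow inverts
the curvature.  Measured CBCT scatter fields are dominated by
very-low-frequency components, so the quasi-flat choice is the physical
one, and it was fixed as the default.

What the surrogate does not model: object-dependence of the kernel,
energy dependence, detector backscatter, and the absolute SPR values of
the physical scanner (hardware quantities).  Conclusions from passing
tests are therefore about the *relative* behaviour of the two geometries
under a controlled scatter process, not about absolute scatter dosimetry.

## Adjacent scatter ratio subtraction

For each collimated frame, 50 detector rows centred 50 mm from the
illuminated band's centre (defaults at the physical pixel pitch; the
desk-scale presets scale the row count to keep the band a few millimetres
wide) are averaged per detector column to give the adjacent scatter
estimate `Is'(u)`.  The ratio `r(u) = Is'(u) / (Ip + Is)(u)` -- the
denominator is the per-column mean over the illuminated band, a choice the
published description leaves open -- is smoothed across columns with a
cubic smoothing spline (generalized cross-validation by default, fixed
`spar` for strict reproducibility) and clipped to `[0, 0.95]`.  Every
pixel in the illuminated rows is multiplied by `1 - r'(u)`.

When the sampling band fits on both sides of the beam, both sides are
averaged (the published description does not say which side the prototype
samples; averaging reduces noise).  Edge sources use the single available
side; the wide-cone configuration has no unexposed rows at all, so its
frames are passed through unchanged and flagged -- the baseline is, by
construction, uncorrectable with this method, which is the point of the
comparison.

The correction is exact when the scatter field is axially flat near the
band and proportional per column to the band's total intensity; both hold
to good approximation under the surrogate with a quasi-flat kernel
(~98% of injected scatter energy removed at desk scale).  The
multiplicative form is pixel-exact only where the collimated band is
filled by the object: beams straddling the end face of a short object
leave pixel-level residuals in the rows where the primary jumps.  The
removal-fraction experiments therefore use a cylinder spanning the
illuminated axial range, which is also the clinically representative case
(a head fills the scan range).

## Reconstruction

All frames of a scan -- from all sources -- enter one system model with a
single matched forward/adjoint pair; the wide-cone baseline is the same
constructor with one source.  SIRT iterates

    x_{k+1} = clip+( x_k + lambda * C * A' * R * (p - A x_k) )

with `R` and `C` the inverse row/column sums of the system weights
(zero-weight rays and voxels excluded) and a nonnegativity clip.  The
iteration count and relaxation used for the published reconstructions are
not reported; the package defaults are `lambda = 1.9` (SIRT converges for
`lambda` in (0, 2); the near-upper value roughly halves the iterations a
unit step needs at desk scale) and 100-320 iterations depending on the
experiment, recorded in each result's provenance.  Offset-detector
redundancy is handled implicitly by the iterative solve over 360 degrees;
no analytic redundancy weighting is applied.  Truncated rays stay in the
data term.

TV denoising minimizes `0.5 ||x - v||^2 + w TV(x)` with Chambolle's dual
projected-gradient scheme (isotropic TV, dual step 1/12 for the 3D
stencil).  The coupling to SIRT is configurable (once after the loop, the
default, or interleaved every k iterations) because the published
description does not specify it.  The quantitative desk-scale experiments
run with `w = 0`: they are noiseless, and TV would only blur the small
structures being measured.

Hounsfield calibration is the standard two-point affine map (water ROI to
0, air ROI to -1000), or the linear map `1000 (mu/muWater - 1)` for
phantoms without an internal water/air reference.

## Quality metrics

All published metric definitions are implemented as pure functions:
uniformity as the standard deviation (n-1) of nine 20 x 20-pixel ROI means
(one central, eight at 60% radius every 45 degrees -- the exact positions
are not published and are recorded with each report; the contrast phantom
moves the ring to 70% radius with a 22.5 degree offset so no ROI touches
an insert); contrast as the absolute insert-background HU difference with
the background taken from two same-radius ROIs (pooled pixels -- pooling
versus averaging separate standard deviations is not specified; pooling
was chosen); CNR as contrast over the pooled background standard
deviation; HU RMSE across the five phantom materials; percentage
improvements to one decimal (recomputation from printed table cells can
differ from printed improvement columns by a few tenths of a point because
the cells themselves are rounded); axial line profiles with a modulation
depth `(max - min)/(max + min + 2000)` on the air-shifted scale; the
effective axial field of view as the maximal contiguous slice range whose
in-cylinder mean HU stays within +-50 HU of the central slice; and
nonparametric Bland-Altman statistics (median difference with 2.5th/97.5th
percentiles, linear interpolation between order statistics -- the
percentile convention is not published and is recorded in the output).

## Problem sizes and what the desk-scale tests show

The test suite and the acceptance script run the full physical geometry
with coarser sampling: 2.4 mm detector pixels, 48-60 views, 48^3 voxel
grids at 4 mm (2 mm and 96^2 x 64 for the disc stack, which needs to
resolve a 4 mm/4 mm alternation), 100-320 SIRT iterations.  These sizes
were chosen so a full property run completes in minutes on one core while
every effect being tested (offset-detector coverage, slab tiling, scatter
cupping, disc-stack undersampling, axial truncation) is well resolved;
`fullScaleConfig()` documents the full-size protocol.  At desk scale the
measured properties are: in-band SPR 0.29 (multisource) vs 0.99
(wide cone); ~98% of injected scatter removed by ASRS; cupping of the
wide-cone water cylinder ~43 HU against ~2 HU after collimation plus
ASRS; disc-stack modulation ratio ~2 at the outermost mutually covered
disc; effective axial coverage 104 mm vs 72 mm (ratio 1.44).  The
disc-stack comparison is made at the outermost disc *inside* the wide-cone
coverage: the phantom's outermost disc falls outside the wide-cone field
of view entirely (consistent with the prototype observation that the first
disc was not visible in that configuration), where a modulation ratio is
undefined.

Because scatter is surrogate and spectra are monoenergetic, these numbers
validate the geometry, sampling and correction machinery -- not absolute
hardware dosimetry or HU accuracy of any physical scanner.  The published
per-scanner HU tables are shipped as `benchmark*()` data and used to
validate the summary-statistic implementations (RMSE, improvements,
uniformity change) against the published arithmetic, which they reproduce
to printed precision.

## Degenerate inputs and numerical conventions

Intensities are clamped at `1e-6 * i0` before the log to avoid
infinities; rays whose system row sum is below 1e-6 mm and voxels with
zero column sum are excluded from the SIRT normalization; SIRT aborts with
a diagnostic if the residual grows past ten times its initial value; the
smoothing spline falls back to the raw (clipped) ratio when fewer than ten
finite columns or a near-constant ratio make a fit meaningless; ties in
the supersampled majority label resolve to the lower material index
(air first).  Random streams are derived per (stage, frame) from the
top-level seed, so every stage is independently reproducible and two runs
of one configuration are bit-identical.

## Known limitations

No beam hardening or polyenergetic spectra; no focal-spot blur, detector
MTF or lag; no Monte-Carlo scatter; no FDK reference reconstruction; no
gantry mechanics (step-and-shoot only); the head phantom is geometric, not
anatomical; absolute published HU tables from the physical scanners are
benchmarks for the arithmetic, not reproduction targets for the simulator.
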
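---
title: "Line-trajectory X-ray tomography for tree-ring measurement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-trajectory X-ray tomography for tree-ring measurement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrotomo)
```

## The problem

Dendrochronology dates wood by matching the pattern of annual ring widths
against dated reference chronologies (crossdating). The rings must be
measured on the transverse section, which on historical objects — panel
paintings, chests, sculptures — is often inaccessible without invasive
surface preparation. X-ray computed tomography can image the rings
non-invasively, but conventional CT requires a full rotation of the object
between source and detector, which rules out large objects.

The line-trajectory (LT) scan sidesteps the rotation: the object is
translated *sideways* between a static cone-beam source and detector, with
the transverse section facing the source, while radiographs are recorded.
The data cover only a narrow angular range (the fan of the cone beam), so
the reconstruction is strongly smeared along the source–detector axis — but
tree-ring surfaces are elongated along the longitudinal wood axis, and when
that axis is aligned with the source–detector axis the smearing runs *along*
the rings. Transverse slices perpendicular to the source–detector axis then
show the ring pattern sharply, which is all dendrochronology needs.

`dendrotomo` implements this measurement chain end to end: phantom
simulation, cone-beam projection, SIRT reconstruction, slice selection, ring
measurement, and crossdating statistics.

## Coordinate conventions

Right-handed world coordinates in mm: `x` from source towards detector, `y`
the horizontal translation axis, `z` vertical; the reconstruction volume is
centred on the origin. The *front* of the object is its minimal-`x` face
(closest to the source, highest magnification). Slice depth is quoted as a
fraction of the object length measured from the front face. Detector pixels
are indexed at their centres; the detector is centred on the source–detector
axis.

An object translation `t` is represented internally as the opposite
translation `-t` of the source–detector pair with a static volume — the two
descriptions are physically identical, and a static volume keeps the
projector contract simple.

## The projector

`forward_project()` computes cone-beam line integrals by Joseph-style ray
tracing: each ray steps along its dominant axis in voxel-index space, one
sample per voxel plane, with bilinear interpolation in the perpendicular
plane and a world path-length weight per step. `back_project()` applies the
exact transpose of the same weights, so the pair is a matched adjoint by
construction — the property SIRT's convergence theory relies on, and one the
test suite asserts directly via the inner-product identity
`<Ax, y> = <x, A'y>`.

Dominant-axis stepping samples each ray roughly once per crossed voxel
plane. For the near-axial rays of an LT scan this resolves every voxel the
ray crosses while keeping the per-ray cost proportional to the volume side,
which is what makes the full 192³ simulation study tractable on a single
CPU. Attenuation is carried in 1/cm and geometry in mm; the projector
converts path lengths so its output is dimensionless line integrals.
Detector pixels are sampled by a single ray through the pixel centre; beam
polychromaticity, scatter, detector blur and noise are all outside the
projector's model (noise can be added to synthetic counts before
`flatdark_correct()` if desired).

## SIRT

`sirt()` solves `A x = b` by the classical simultaneous iterative
reconstruction technique

    x_{k+1} = x_k + lambda * C A' R (b - A x_k),

with `R` and `C` the inverse row and column sums of `A` (computed once per
geometry by projecting/backprojecting all-ones arrays; sums below 1e-12
invert to zero so that rays and voxels outside the coverage stay inert),
`x_0 = 0`, `lambda = 1`, no constraints, and a fixed iteration count: 50 for
the simulation study, 100 for laboratory-scale scans, 400 for
high-resolution plank work. There is no stopping rule — fixed counts make
runs reproducible and match established practice with this algorithm. The
per-iteration residual norms are returned (`residual_history()`); with
consistent data and `lambda` in (0, 2) they are non-increasing, which the
tests assert. A residual growing beyond 10x its initial value aborts with a
diagnostic.

Cuboid ("anisotropic") voxels — elongated 1:1:4 along the wood's
longitudinal axis — are supported simply by giving the grid unequal voxel
sizes; because the wood structure is nearly invariant along that axis at
voxel scale, transverse ring measurements are essentially unchanged while
memory and time drop fourfold, which the test suite verifies (ring widths
from 1:1:4 and isotropic reconstructions agree within 2% on average).

## The phantom

`build_phantom()` renders a two-phase model of wood: perfectly concentric
rings around a pith axis, each ring's outer `latewood_fraction` (default
0.3) at the latewood attenuation `mu_late` (default 0.6/cm) and the rest at
`mu_early` (default 0.3/cm); background 0 outside the outermost ring. The
defaults are plausible softwood values; only the earlywood/latewood contrast
matters for the geometry of ring detection. The tree-ring tilt `alpha`
rotates the pith axis about the vertical axis (about the volume centre), and
`pith_offset` moves the axis in the transverse plane — including outside the
volume, mimicking planks cut far from the pith.

Voxels take the value at their centre, with no partial-volume averaging.
That keeps the phantom an exact analytic oracle — `ground_truth_widths()`
intersects any measurement path with the ring boundary surfaces in closed
form — at the price of aliased edges. One practical consequence: a latewood
band much narrower than a voxel may contain no voxel centres along a path
and effectively vanish; generating series should keep ring widths at or
above about three voxels for faithful round trips. What the phantom does
*not* emulate: real wood anatomy (vessels, knots, density gradients within a
ring), measurement noise, polychromatic physics. Passing the phantom studies
therefore demonstrates the geometric and algorithmic soundness of the chain,
not robustness to every property of real radiographs.

## Preprocessing and calibration

`flatdark_correct()` converts raw counts to line integrals with
`p = -log(max((I - D)/(F - D), eps))`; `eps = 1e-6` floors dead pixels
(where flat equals dark, or counts dip below dark) without affecting
well-exposed pixels.

For scans on uncalibrated setups, `estimate_geometry_from_ruler()` mimics
the nail-ruler protocol: a lath with metal nails every centimetre
(`nail_spacing = 10` mm) scanned alongside the object. Nails are detected as
prominent attenuation peaks in a designated detector row band (local maxima
above median + 3·MAD of the band profile); the mean projected nail spacing
gives the front magnification, and the translation between consecutive
frames comes from the 1D cross-correlation of the band profiles, refined to
sub-pixel precision by a parabolic fit around the correlation peak. The
parabolic refinement is this package's convention — integer-pixel
correlation is the specified operation, and the refinement adds accuracy at
no cost (the tests allow it 0.01 px of bias).

## Slice selection and ring measurement

Because the front of the object has the highest magnification, resolution is
best near the front — but the limited-angle smearing means the very front
face is not the sharpest plane; planes around 25% depth usually are, which
is the default `depth_fraction` of `extract_slice()`. In laboratory
practice the slice is chosen by eye together with a dendrochronologist;
`rank_slices_by_sharpness()` automates the choice with a Tenengrad focus
score (mean squared gradient magnitude), a convention of this package. The
score rewards any strong gradients, including the streak artifacts that
limited-angle SIRT develops in the weakly covered rear of the volume, so the
scan pipeline ranks candidate depths only over the front half of the object
by default (`candidate_fractions = seq(0.1, 0.5, 0.05)`), where resolution
is best; an explicit `slice_fraction` always overrides the ranking.

Ring measurement follows the manual protocol in automated form:

1. `profile_along_path()` samples the slice bilinearly along a measurement
   path drawn perpendicular to the ring boundaries (default step: half a
   pixel).
2. `detect_boundaries()` finds prominence-filtered latewood peaks (default
   prominence: 10% of the profile's dynamic range; default separation:
   0.2 mm, below the narrowest rings of slow-grown conifers) and places each
   boundary on the falling latewood-to-earlywood edge after the peak, at the
   crossing of the half level between peak and following trough. On a
   profile sampled along a grid line the interpolated values are piecewise
   linear, so the half-level crossing interpolates to sub-pixel positions
   where a steepest-gradient argmin would quantize to the sample grid; on a
   smooth edge the half level *is* the steepest point. Any consistent edge
   landmark yields telescoping widths (their sum equals the distance between
   first and last boundary), which is the property crossdating needs.
3. `measure_rings()` turns boundary positions — detected or manually placed
   coordinate points — into a width series.

The innermost ring has the pith, not a latewood edge, as its inner boundary,
so an automated radial measurement recovers one width fewer than the
generating series; comparisons align series at the bark end. As in the
laboratory protocol, the pipeline averages profiles over three neighbouring
slices (±3% depth; for tilted rings each slice's analytically known lateral
shift is compensated first), which suppresses reconstruction noise at no
resolution cost because the pattern repeats along the pith axis.

## Crossdating statistics

`bp_normalize()` divides each width by a centred five-term running mean and
takes the natural log, removing the growth trend. At the series edges the
window shrinks symmetrically; where a symmetric window would hold fewer than
three values (the outermost ring at each end), the nearest three values are
used — the historical procedure leaves edge handling open, so this is a
documented convention of the package.

`tbp()` is the Baillie–Pilcher t-value: the Pearson correlation `r` of the
two BP-normalized series converted to `t = r sqrt(n-2) / sqrt(1-r^2)`. The
statistic diverges at `r = 1`, so values above 100 are capped at 100 — the
cap applies to the t-value, not to `r` — making 100 the sentinel for
identical series at any overlap length.

`gleichlaufigkeit()` scores the n−1 year-to-year changes: 1 when both series
move with the same strict sign (or both are flat), ½ when exactly one is
flat, 0 when they oppose; Gl is 100 times the mean score. The tie rules are
the standard dendro convention. Under the null of independent series the
score variance is 1/(4(n−1)), giving the normal deviate
`z = (Gl/100 - 1/2) · 2 sqrt(n-1)` and a one-sided upper-tail p-value;
p < 0.0001 is flagged `###` in crossdating tables.

`crossdate_sliding()` evaluates every offset with at least `min_overlap`
overlapping rings (default 30; never below 5, the BP window minimum),
normalizing the overlapping segments per offset, and ranks by TBP, with ties
broken by Gl and then by longer overlap. Offsets where a segment is constant
after normalization carry no correlation information and are omitted from
the table. `rbar()` reports the mean pairwise correlation of BP-normalized
series, as quoted alongside TBP and Gl when several measurements of one
sample are compared. Two same-sample measurements are expected to show
TBP > 10 and Gl > 75% even for short overlaps; identical series give exactly
TBP = 100 and Gl = 100%.

## Study conditions and problem sizes

The package's simulation study (`run_simulation_study()`) reproduces the
tilt-robustness experiment at sizes chosen to run in minutes on one CPU:

| quantity | value |
|---|---|
| grid | 192 × 192 × 192 voxels of 0.5 mm (96 mm cube) |
| generating series | 18 rings, mean 2.2 mm, CV 0.25, lognormal |
| cone angle | 9° (half-fan), SOD 500 mm, SDD 650 mm |
| detector | 96 × 192 px; translations: 64 positions spanning fan + object |
| SIRT | 50 iterations, λ = 1, unconstrained |
| tilts | 0°, 8°, 15° |
| slice | 25% depth; profiles averaged over ±3% |

With 18 rings of mean 2.2 mm at 0.5 mm voxels the narrowest rings approach
the resolution limit discussed above, which is the realistic regime — the
interesting claim is that tilt, not resolution, drives the breakdown. The
study compares each tilted slice against the untilted one by Pearson
correlation after compensating the known lateral shift of the tilted pith
axis in the slice plane (without the compensation the shift itself, a ring
period or more at 15°, would dominate the comparison). Expected outcome,
asserted by the acceptance tests: similarity and ring-recovery accuracy
degrade monotonically with tilt; recovery stays below 8% mean absolute
relative error for tilts clearly under the 9° cone angle and fails that
bound at 15°.

A companion check reconstructs one plank-like phantom (48 × 96 × 48 mm,
0.5 mm voxels, pith outside the sample as in real planks) both with the LT
trajectory and with a full-rotation circular CT trajectory (180 angles,
100 iterations each) and crossdates the two measured series: they must
match at lag 0 with TBP > 10 and Gl > 75%. Because a circular CT resolves
the object through a detector whose effective sampling at the object is
coarser than the voxel size, this fixture keeps ring widths near 3–4.5 mm —
several times both modalities' sampling — so the comparison probes the
trajectories, not the resolution limit.

The number of translations (64) is a deliberate relaxation of the sampling
rule used for real scans — that a point on the object front should move less
than one detector pixel between projections (`max_translation_step()`).
Synthetic noiseless data tolerate much sparser sampling, and the relaxation
is what makes the 192³ study a desk-scale computation;
`satisfies_sampling_rule()` reports the rule so real acquisitions can honour
it.

## File formats

Ring-width series read/write as two-column CSV (exact round trip) and as
Tucson decadal RWL (0.01 mm units, 8-character identifiers, 999 terminator —
the ITRDB interchange dialect). Volumes and projection stacks read/write as
multi-page 32-bit TIFF with a plain-text sidecar holding the array shape,
voxel sizes and a min–max scale/offset pair (TIFF storage is normalized to
[0, 1]; round trips are exact to about 1e-9 relative). Geometries serialize
as `key: value` text blocks, exactly round-trippable. Manual measurements
enter as CSV coordinate points. Pipeline runs write a YAML manifest with
every parameter and seed, sufficient to reproduce the run bit for bit.

## Known limitations

* The projector is monochromatic and noise-free; beam hardening, scatter and
  detector effects of real scanners are not modelled.
* The phantom's two-phase rings omit intra-ring density gradients and wood
  anatomy; boundary detection tuned on phantoms may need parameter changes
  (prominence, separation) on real reconstructions.
* Automated boundary detection assumes a measurement path roughly
  perpendicular to the boundaries with the latewood denser than the
  earlywood; strongly curved ring portions should be measured along a
  different path, or manually via coordinate points.
* The pith-side ring of an automated radial measurement is not recovered
  (no latewood edge on its inner side).
* Slice sharpness ranking is a heuristic stand-in for expert inspection;
  an explicit slice choice always takes precedence.
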
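---
title: "Measuring wound area from RGB-D captures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wound area from RGB-D captures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundarea)
```

## The measurement model

Chronic-wound care tracks healing through the wound's surface area, but
contact planimetry (transparent film traced with a marker, then
digitized) is slow and unpleasant for the patient. A depth-equipped
camera allows contact-free planimetry: a segmentation model outlines the
wound in the colour image, the co-registered depth map supplies a range
for every border pixel, and geometry does the rest.

The pipeline in this package makes three modelling assumptions:

1. **Pinhole optics.** A pixel (u, v) with depth z back-projects to the
   camera-frame point ((u − o~x~) z / f~x~, (v − o~y~) z / f~y~, z).
   No lens-distortion terms are modelled; consumer RGB-D frameworks
   deliver rectified images. Depth is the z-coordinate along the
   optical axis, not the ray length; `ray_length_to_z_depth()` converts
   range-style sources.
2. **A planar wound bed.** The 3D border points are summarized by the
   least-squares plane z = a x + b y + c — the multiple linear
   regression of z on (x, y). Real wounds are not exactly planar; the
   plane is the model, and the RMS vertical residual reported by
   `summary()` of a fit is the diagnostic for how far a wound departs
   from it.
3. **Tilt-corrected shoelace area.** After orthogonal projection onto
   the fitted plane, the projected border's xy-shadow area (the cyclic
   2×2 determinant sum, halved) is rescaled by 1 / cos θ with
   cos θ = 1/√(a² + b² + 1). For a polygon lying on the plane this
   rescaling is exact, because the projection plane → xy-plane is
   linear with Jacobian cos θ.

The signed determinant sum depends on vertex orientation; its absolute
value is used, so clockwise and counter-clockwise borders measure
alike. Self-intersecting borders are not repaired — the shoelace value
is still well defined but counts enclosed regions with multiplicity —
and polygon inputs that self-intersect are flagged
(`self_intersecting_contour`) rather than altered. Traced mask
boundaries cannot self-intersect by construction.

World coordinates are metres internally; areas are reported in cm²
(× 10⁴). The default extrinsics are the identity: unless a capture
pipeline defines a separate world frame, the camera frame *is* the
world frame.

## From mask to contour

Segmentation output arrives either as a binary mask or as a LabelMe
polygon annotation. For masks, `extract_contour()`:

* selects the **largest 8-connected component** (clinical captures hold
  one wound per image; smaller components are specks, and a
  `multiple_components` flag records their presence — an option allows
  measuring a chosen component instead);
* traces its outer boundary by **Moore-neighbour tracing** with Jacob's
  stopping criterion, a deterministic standard method, yielding an
  ordered closed polygon of pixel centres. Interior holes are ignored:
  the outer margin is the clinically traced contour.

Depth at each border vertex is sampled at the nearest pixel, falling
back to the median of valid depths in the 3×3 neighbourhood (time-of-
flight maps have holes on dark or oblique surfaces), and dropping the
vertex as a last resort; more smoothing than that would invent data.
If more than half the vertices drop, or fewer than three survive, the
measurement fails with an `insufficient depth` error rather than
returning a number built from too little evidence.

## Tunable parameters

All knobs live in `measurement_config()`:

| parameter | default | meaning |
|---|---|---|
| `frame_fill_warn` | 0.20 | warn when the mask covers less of the frame; small, distant wounds segment and measure unreliably, so captures should be retaken closer |
| `min_cos_theta` | 0.10 | refuse planes tilted beyond ≈ 84°; 1/cos θ amplifies noise without bound and the z = f(x, y) plane form degenerates |
| `contour_step` | 1 | keep every k-th contour vertex; decimation for very long borders |
| `max_drop_fraction` | 0.5 | tolerated fraction of depth-less border vertices |
| `boundary_correction` | TRUE | rasterization-bias correction, below |
| `resize_to` | off | file-level standardization (the clinical pipeline used 512 × 512); intrinsics are rescaled along with the images |
| `depth_scale` | 10⁻³ | metres per stored unit for 16-bit PNG depth (millimetre encoding) |

The frame-fill rule is a warning, not a failure: it mirrors a user
instruction ("move closer"), and a measurement of a small wound is
still a measurement.

## Numerical choices

**Boundary correction.** A traced contour passes through the *centres*
of boundary pixels, so the polygon it encloses omits a half-pixel band
around the region — a systematic under-measurement of roughly
perimeter/2 pixels, which is ~0.9 % for a wound filling 20 % of a
512 × 512 frame. `measure_wound_area()` therefore multiplies the
measured area by (component pixel count) / (2D shoelace area of the
traced contour). The pixel count is an unbiased estimate of the
region's pixel area, so the ratio cancels the band bias; the residual
error is an order of magnitude smaller. The correction only applies to
mask inputs — polygon annotations are already continuous coordinates —
and can be disabled.

**Plane fitting.** The regression is solved by QR factorization
(`lm.fit`), not by explicitly forming the normal equations; the normal
equations (AᵀA)x = AᵀB are retained in the test suite as the
independent oracle the factorization must match. A rank-deficient
design — border points whose xy-footprint is collinear, i.e. a
near-vertical plane — is an error.

**Dual-route area check.** The tilt-corrected shoelace area is verified
against an independent formula, half the norm of the cyclic cross-
product sum (`polygon_area_3d()`), which never references the plane
coefficients. The two agree to 10⁻⁹ relative error on randomized planar
polygons spanning four orders of magnitude in size.

**Degenerate inputs.** Empty masks, single-pixel components, polygons
with fewer than three vertices, zero-area polygons, non-positive
depths, and non-orthonormal rotations all raise classed errors
(`wa_*`), which the CLI maps to distinct exit codes.

**Zero-denominator metrics.** For segmentation metrics on empty/empty
mask pairs the package returns 1 with a warning (configurable to an
error), matching the ε-smoothed Dice loss, which treats empty/empty as
a perfect match.

## The synthetic-scene generator

`render_scene()` renders a planar polygonal "wound" exactly: each pixel
ray is intersected with the scene plane in closed form
(z = c / (1 − a d~x~ − b d~y~)), the mask is the even-odd polygon test
in plane-local coordinates, and Gaussian noise/quantization are applied
afterwards under a seed (same seed, bit-identical scene). Ground truth
— polygon area and plane coefficients — is analytic, so end-to-end
recovery can be asserted tightly.

`tilted_wound_scene(area, tilt, fill)` is the parametric front end used
by the validation grid. Two design points matter:

* The wound polygon is constructed as the **exact preimage on the
  tilted plane of a centred square drawn in the image**, and the
  viewing distance follows in closed form from the requested area
  (the preimage scales linearly with distance). This realizes *any*
  combination of area, tilt < 90° and fill < 1 without the wound ever
  clipping the frame; a plane-local rectangle, by contrast, cannot
  reach steep tilt at high fill inside any realistic field of view.
  At steep tilts the on-plane polygon becomes an elongated
  quadrilateral — exactly what a steeply viewed wound looks like.
* The image square is **rotated 5° by default**: a square aligned with
  the pixel grid rasterizes with a systematic count error of up to one
  pixel row per edge (±0.85 % at 20 % fill), which would contaminate
  sub-percent validation with an artefact of the fixture rather than
  the method.

The generator's camera defaults to a 512 × 512 frame with
f~x~ = f~y~ = 1000 px — a moderate ≈ 29° field of view that keeps a
60°-tilted wound at 80 % fill well away from the plane's horizon in the
image. Distances then range from about 1 cm (a 1 cm² wound filling 80 %
of the frame must be captured very close) to about 0.4 m, spanning the
clinically reported range of wound sizes (~0.7–83 cm²).

What the generator does *not* emulate: segmentation errors (masks are
geometrically exact), textured or curved wound beds, LiDAR multipath
and edge artefacts, motion blur, or occlusion. Passing the recovery
grid therefore validates the *geometry* of the pipeline — given a
faithful mask and clean depth, the area is right — and says nothing
about segmentation quality on real photographs, which is evaluated
separately with the Dice/IoU metrics and, clinically, by the bundled
manual-vs-automatic comparison.

## Validation problem sizes

The test suite and the acceptance script use: a 36-scene grid (areas
{1, 20, 80} cm² × tilts {0, 20, 40, 60}° × fills {0.2, 0.5, 0.8}),
noiseless and with σ = 2 mm depth noise; 100–200 random planar polygons
for the dual-route area check; 50 random camera poses for the
round-trip identity; and 80-point noisy plane fits against the
normal-equations oracle. Noiseless recovery errors stay below 0.2 %
across the grid; with 2 mm noise the median relative error is ≈ 0.1 %
and the worst scene ≈ 2–4 % (small wounds at 20 % fill, where the
capture distance is a few centimetres and 2 mm of noise is a large
relative depth error).

## The clinical reference table

`clinical_wound_areas()` bundles a 20-wound prospective comparison of
manual planimetry against the automatic pipeline under two segmentation
models. Both the published per-wound areas (rounded to 0.1 cm²) and the
published per-wound relative errors are stored, because the published
errors were computed from unrounded areas: re-deriving wound 2's error
from the rounded areas gives 5.1 % where 3.6 % was published. Summary
statistics therefore default to the published per-wound errors
(`use_printed_re = TRUE`). One published summary value is itself a
rounding casualty: the outlier-removed U-Net mean relative error was
published as 26.2 %, while the published per-wound errors average to
26.6 %; the package reports what it computes. The mean-relative-error
convention is percent; the SD convention is a fraction — the mixed
convention of the source table is kept to avoid silent unit surprises.

Wounds 16 and 20 are flagged outliers: one wound too small in the frame
for segmentation to succeed (the origin of the 20 % frame-fill rule),
one photographed against a bloody, gauze-strewn background. Exclusion
is always explicit (`exclude = c(16, 20)` or `--exclude outliers`).

## Known limitations

* A single plane cannot follow deep, undermined or tunnelled wounds;
  the area of a strongly curved bed is under-measured. The RMS plane
  residual is the available warning signal.
* Depth and mask must be co-registered; the package trusts the
  capture stack's calibration and offers no re-registration.
* Areas inherit the depth sensor's scale accuracy; a systematic depth
  bias of ε scales areas by (1 + ε/z)².
* The bundled clinical table is a fixed 20-wound reference for the
  evaluation statistics, not a validation of any new capture setup.
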
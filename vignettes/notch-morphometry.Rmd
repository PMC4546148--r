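---
title: "Measuring the lateral femoral notch sign: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the lateral femoral notch sign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchmorph)
```

## The measurement problem

An ACL rupture often drives the lateral femoral condyle against the
posterolateral tibial plateau, leaving an impaction fracture of the
subchondral cortical bone — visible on a lateral radiograph as an
unusually deep condylopatellar sulcus (the *lateral femoral notch
sign*) and on MRI as a depressed stretch of the subchondral bone
contour. `notchmorph` turns per-slice segmentations of that surface into
defect metrics (extent, depth, areas, volume) and an anatomical
location, and provides the radiographic screening measurement that
selects knees for MRI analysis in the first place.

Two surfaces matter for an indentation defect. The *primary* surface is
the reconstructed, pre-injury bone surface spanning the defect (the
bridged contour); its area is the share of the condyle affected and the
numerator of percent-of-condyle. The *concave* surface is the actual
depressed bone; for an indentation it is always at least as large as
the primary surface it replaced.

## Radiographic sulcus depth

The tangential-line technique draws a line across the sulcus touching
the convex articular margin on both sides and measures the perpendicular
distance to the deepest point. We implement the tangent as a convex-hull
edge: the hull chain on the declared articular side of the (open)
profile is computed, index gaps in the chain are concavities, and the
gap with the largest perpendicular deviation is the sulcus (ties go to
the more anterior concavity). Convex profiles therefore measure exactly
0 mm. Points collinear with a hull chord are pulled into the chain so
the tangent touches the concavity rim rather than a distant hull corner.

Two consequences are worth noting. First, the profile must declare
which side the bone is on (`outward` in `sulcus_profile()`); an open
curve alone does not determine it. Second, on a *convex* condyle the
tangent chord sits below the intact arc by the chord's sagitta, so the
technique reads less than the radial indentation depth: a spherical
indentation of radial depth 3 mm on a 20 mm condyle measures about
2.06 mm from the tangent. This is a property of the radiographic
technique itself, and consistent with radiographic screening thresholds
(1.5 mm) being much smaller than MRI-measured defect depths (~3 mm).

The notch-sign threshold is 1.5 mm *inclusive*. Sources phrase the
cut-off both as "≥ 1.5 mm" and "over 1.5 mm"; we adopt the inclusive
reading and expose the threshold as an argument.

## Slice-wise bridging

The depressed interval of a contour is either taken from expert marks
in the exchange file (authoritative when present, since marking is a
radiologist's call) or detected as the contiguous run of vertices
deviating from the articular-side convex hull, extended outward to the
hull-touching vertices. The default detection threshold of 0.3 mm sits
just above the finest clinical in-plane resolution (0.29 mm), so
resolution-scale jitter cannot trigger spurious marks.

The bridge is a cubic interpolating spline (`stats::splinefun`, FMM end
conditions) through 5 intact flank vertices per side, parameterized by
cumulative chord length, evaluated across the gap at the contour's
native point density; nearly collinear flanks (deviation < 1e-6 mm)
fall back to the straight chord. Five flank points keep the fit local —
enough to carry curvature across the gap without importing far-away
shape. On a circular arc of condylar radius the spline stays within a
few hundredths of a millimeter of the true circle across a
defect-sized gap.

Per-slice depth is the maximum distance from depressed vertices to the
bridge polyline — i.e. measured perpendicular to the reconstructed
surface, not along the image vertical; the choice matters only for
steep bridges and is the geometrically meaningful one. The per-slice
gap area is the shoelace area of the closed bridge + reversed-depressed
polygon; a crossing between the two curves is reported as an error
naming the slice, since it indicates an inconsistent mark.

## 3D reconstruction and defect metrics

Surfaces are built by strip triangulation between adjacent slice
contours after resampling each contour to K = 200 points uniformly in
arc length — the standard stacked-contour construction in cartilage and
bone morphometry. No end-caps are added: the segmented structure is an
open sheet. K = 200 puts the in-plane resampling step (~0.2 mm for a
40 mm contour) at or below typical in-plane resolution; halving it
moves areas by well under 0.5 %.

Defect volume integrates per-slice gap area over slice position with
the trapezoidal rule. Slices without a mark contribute zero, so the
integrand tapers naturally at the defect margins instead of being
truncated at the outermost marked slices. The medio-lateral width adds
one slice spacing to the span of defect-bearing slice positions (each
slice represents a slab), so a single-slice defect has nonzero width;
the antero-posterior length is the largest AP projection of the
bridge chord, per slice — extents are axis projections, not 3D chords.

On phantoms (below), all five defect quantities land within 5 % of
their closed forms at 0.5 mm spacing / 0.1 mm step, and volume stays
within 20 % at clinical-like 3.3 mm spacing.

## The six-segment partition

Plane 1 passes through the trochlear notch, spanned by the
femoral-shaft direction and the vector connecting the most posterior
points of the medial and lateral condyles; it separates trochlea
(anterior) from condyle. Plane 2 is parallel, offset by 60 % of the
signed notch-to-posterior distance measured *from the notch toward the
posterior points* — so the central, weight-bearing segment spans the
first 60 % of that distance behind plane 1 and the posterior segment
the rest. The internal/external split is the midpoint of the segmented
surface's medio-lateral extent (the surface's, not the defect's).
Internal means medial; the lateral side is identified from the
posterior landmark pair.

Triangles are assigned to segments by centroid, without splitting at
plane crossings: assignment error vanishes with mesh refinement, and in
exchange the six segment surfaces and defect areas are *exactly*
additive to the totals (a property the cohort consistency checks rely
on). Per-segment defect volume is distributed in proportion to each
segment's primary-area share — also exactly additive; a depth-weighted
attribution would differ slightly for defects straddling a boundary,
but has no additive guarantee. Per-segment extents and depth are
computed from the depressed vertices falling in the segment.

The per-knee location call is the segment with the largest primary-area
share; exact ties break in the order CE, CI, AE, AI, PE, PI
(central-external first, the most common clinical location).

## Cohort screening and consistency checks

Screening keeps knees with sulcus depth at or above threshold *and*
MRI confirmation, mirroring the clinical funnel in which suspicious
radiographs without MRI evidence are excluded. Summaries use n−1
standard deviations (reported missing for a single knee) and average
per-segment tables over *all* knees, zeros included — the convention
under which segment columns remain additive to the cohort totals.
Reported precision follows clinical convention (one decimal); machine
outputs keep full precision.

`consistency_checks()` verifies that a summary's per-segment table sums
to its totals (surfaces, affected areas, concave areas, volumes), that
percent-of-condyle equals 100 × affected/total, and that mm²/cm² value
pairs agree. Tolerances default to accumulated one-decimal rounding
(0.05 per printed value entering a check, with propagation for the
ratio); full-precision summaries can be checked at ~1e-9. The package
ships the published reference table for a 50-knee cohort
(`reference_segment_table()`); its printed percent-of-region column is
not reproducible from the other printed columns and is deliberately
excluded from all checks.

## The phantom: what it does and does not emulate

The phantom models the condyle as a band of a sphere (radius R, default
20 mm; medio-lateral half-width 15 mm; articular arc 30°–150°) and the
impaction as a spherical indentation: surface points inside an indenting
sphere (radius r, default 10 mm; depth t, default 3 mm) are projected
onto it. Within each sagittal slice the indent sphere cuts an in-plane
circle, and the projection is done in-plane, so sampled points lie
exactly on the analytic surfaces and the annotated defect interval is
the exact geometric intersection. Every target quantity then has a
closed form: cap areas 2πRh_R and 2πrh_r over the common boundary
circle, the classical sphere–sphere lens volume, depth t, and hat-box
band areas — all verified independently against a 0.05 mm voxelization
(volume, to 0.02 %) and a triangulated-band oracle (areas).

Defaults emulate the study conditions: sagittal slices (clinical
spacing 3.0–4.8 mm, fine validation at 0.5 mm), in-plane steps matching
clinical resolution 0.29–0.70 mm (fine 0.1 mm), defect depth 3 mm
matching the reported mean, and an indent direction in the mid-sagittal
plane of the band aimed at the central articular surface. Optional
isotropic Gaussian point jitter (seeded; default off) exercises
robustness. The same spec and seed always reproduce identical output.

What the phantom does *not* emulate: MR intensity formation and
partial-volume effects, segmentation-software behavior, anatomical
shape variation (a condyle is not a sphere), cartilage, bone-bruise
(non-cortical) lesions, or observer variability in marking. Passing
phantom tests therefore demonstrates that the *geometry pipeline* is
correct and convergent under realistic sampling — not that clinical
inter-reader agreement would be high.

## Numerical choices and degenerate inputs

- Collinearity tolerances: 1e-9 mm for pulling hull-collinear points
  into the chain; 1e-6 mm flank deviation for the chord fallback.
- Zero-length segments are collapsed before arc-length resampling;
  degenerate marks (adjacent vertices) yield zero gap area rather than
  an error.
- A defect-free knee returns all-zero metrics, not an error; an empty
  segment likewise reports zeros.
- Contours are open curves; profiles declare their articular side
  explicitly. Slice positions must be strictly increasing; violations
  are rejected at file load with the offending slice named.
- All randomness (phantom jitter) flows from the single spec seed; the
  global RNG state is restored afterwards.

## Problem sizes used in validation

The shipped tests validate on phantoms of up to 61 slices × ~420 points
(0.5 mm / 0.1 mm sampling, K = 200 resampling; the full suite runs in a
few seconds), a 3 × 3 geometry grid at 0.5 mm / 0.2 mm, and
clinical-like 3.3 mm / 0.33 mm sampling; the voxel oracle uses a
0.05 mm grid over the lens bounding box. These sizes were chosen so
that discretization error sits well below the tolerances being
asserted while keeping the suite quick to run routinely.

## Known limitations

- The bridge is a geometric reconstruction; where the true pre-injury
  surface was locally non-convex (a shallow native sulcus is normal),
  depth is measured against the bridge, which may slightly overestimate
  the injury-attributable depression — the same caveat applies to the
  clinical technique.
- Tangential radiographic depth underestimates radial indentation depth
  on convex profiles (see above); the two measurements are related but
  not interchangeable.
- Centroid assignment leaves a one-triangle-wide ambiguity band along
  partition boundaries (vanishing with K).
- DICOM/NIfTI import is out of scope; the JSON exchange format is the
  single entry point for segmentations, leaving room for external
  converters.
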
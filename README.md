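# notchmorph

Quantitative morphometry of the **lateral femoral notch sign** — the
impaction fracture of the lateral femoral condyle that accompanies
anterior cruciate ligament (ACL) rupture — from sagittal knee-MRI
segmentations and lateral-radiograph condyle profiles.

The package is for musculoskeletal imaging researchers who have (or can
digitize) per-slice contours of the lateral femoral subchondral bone
surface and want reproducible defect metrics: extent, depth, surface
areas, volume and anatomical location.

## What it computes

**Radiograph screening.** On a digitized lateral-radiograph profile, the
condylopatellar sulcus depth is measured with the tangential-line
technique: the tangent is the convex-hull edge of the profile spanning
the deepest concavity, and the depth is the perpendicular distance from
that line to the deepest point. A depth ≥ 1.5 mm (inclusive, about three
standard deviations above the ~0.5 mm intact sulcus) calls the notch
sign positive.

**Per-slice defect geometry.** In each sagittal slice the depressed
portion of the bone contour is marked (expert marks from the exchange
file, or automatic convex-hull detection) and bridged with a cubic
spline through *n* intact flank vertices per side, approximating the
bone surface under normal anatomical conditions; the bridge falls back
to the straight chord when the flanks are collinear. Per-slice depth is
the maximum distance from the depressed curve to the bridge; the gap
area is the planar area enclosed between the two curves.

**3D reconstruction and metrics.** Stacked contours (bridged across
defects) are resampled to *K* points by arc length and joined by strip
triangulation. With per-slice gap area A(x) at slice position x:

- total condyle surface = Σ triangle areas (cm²),
- primary ("green line") defect area = strip area over the bridge curves,
- concave ("pink line") defect area = strip area over the depressed curves,
- volume = ∫ A(x) dx by the trapezoidal rule across slice positions (mm³),
- depth = max per-slice depth; AP length / ML width = maximal
  antero-posterior and medio-lateral extents (slab convention),
- percent of condyle = 100 · primary area / total area.

**Six-segment localization.** A plane through the trochlear notch
(spanned by the femoral-shaft axis and the inter-condylar
posterior-points vector) separates the trochlea from the condyle; a
parallel plane at 60 % of the notch-to-posterior distance separates the
central weight-bearing segment from the posterior segment; a split at
50 % of the medio-lateral extent gives internal (medial) and external
(lateral) halves — segments AI, AE, CI, CE, PI, PE. Triangles are
assigned by centroid, so segment metrics are exactly additive to the
totals, and the defect is localized to the segment holding the largest
primary-area share.

**Phantom ground truth.** A synthetic condyle (spherical band, radius R)
indented by a sphere of radius r to depth t has closed-form defect
metrics (spherical caps and the sphere–sphere lens volume), so the whole
pipeline is validated end to end against analytic truth at both
fine (0.5 mm / 0.1 mm) and clinical-like (3.3 mm / 0.33 mm) sampling.

## Worked example

```r
library(notchmorph)
ph <- generate_phantom(phantom_spec())        # R=20, r=10, t=3 mm
summary(measure_knee(ph$slices, ph$landmarks))
```

```
Knee morphometry
----------------
<notch_knee> condyle surface 12.6 cm^2
<defect_metrics>
  extent:  11.8 mm (a.p.) x 12.5 mm (m.l.), depth 3.0 mm
  areas:   primary 1.2 cm^2 (9.5% of condyle), concave 1.3 cm^2
  volume:  177.8 mm^3
  primary location: CE
```

The closed-form truth for this phantom is depth 3.0 mm, primary area
118.7 mm², concave area 129.2 mm² and volume 178.8 mm³
(`analytic_lens_metrics(20, 10, 3)`), so the pipeline recovers every
defect quantity to well within 1 %. The per-segment table (printed by
`summary()`) splits the same quantities over the six segments and sums
back to the totals exactly.

A shell entry point wraps the same functions:

```sh
exec/notchmorph phantom --out knee.json --seed 7
exec/notchmorph measure --in knee.json
exec/notchmorph xray --profile profile.csv
```

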
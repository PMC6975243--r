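---
title: "Sphere-fit morphometry of articular facet surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sphere-fit morphometry of articular facet surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetmorph)
```

## The measurement problem

Small articular surfaces — here the carpometacarpal (CMC) facets of the
hamate and the bases of the fourth and fifth metacarpals — are a few to
twenty millimetres across and well captured by laser surface scanning at
roughly ±100 µm accuracy. Clinically relevant questions about these
joints (how congruent they are, whether the fifth CMC is a bicondylar
construct permitting flexion with limited supination, whether the dorsal
fourth-CMC articulation is flattened) reduce to a small set of
measurements on triangle meshes of individual facet patches:

* **surface area** of the patch;
* **length** and **width**, defined as arc lengths of mid-plane
  cross-sections;
* the **radius of curvature (ROC)**: the radius of the sphere best
  fitting the patch, with the **mean error** (mean absolute orthogonal
  residual, also expressed as a percentage of the radius) quantifying
  how spherical the surface really is;
* a **two-sphere (bicondylar) decomposition** with per-condyle radii,
  area fractions, and the **angle of divergence** between the condyles;
* a **three-point ROC** along a single cross-section, for surfaces that
  are curved in only one direction (the intermetacarpal facet is nearly
  cylindrical);
* the **inter-facet angle** between two adjacent facets of one bone.

`facetmorph` implements this pipeline end to end, together with a
ground-truthed synthetic-surface generator, so every stage is testable
without access to cadaver scans.

## Geometry conventions

A disarticulated facet has no intrinsic anatomical axes, so every
measurement is made relative to an explicit `anatomical_frame`:

* the **sagittal** axis is the length direction (dorsal–volar on these
  facets), the **coronal** axis the width direction (radial–ulnar, with
  +coronal = ulnar by convention), and the **normal** axis points out of
  the surface;
* the frame origin is the area-weighted surface centroid;
* the **mid-sagittal plane** is spanned by the sagittal and normal axes
  (its cross-section is the length), the **mid-coronal plane** by the
  coronal and normal axes (its cross-section is the width). The
  mid-axial section used for the three-point ROC coincides with the
  mid-coronal plane of that facet's frame.

Axes come either from a landmark orientation file (JSON with
`dorsal_volar` and `radial_ulnar` vectors, re-orthogonalised by
Gram–Schmidt and rejected if more than 10° from orthogonal) or, by
default, from vertex PCA: sagittal = largest-variance direction,
normal = smallest, flipped to agree with the mean face normal. PCA signs
are arbitrary, so analyses that depend on the radial/ulnar or
dorsal/volar *direction* (bicondylar labelling, flattening detection)
should supply landmarks; the `source` field records which path was
taken, and a near-circular patch whose two smallest eigenvalues are
equal raises an error advising a landmark file.

## Sphere fitting

The ROC minimises the geometric objective
\(\sum_i (\lVert p_i - c\rVert - r)^2\). The algebraic (Kåsa) sphere —
linear least squares on \(\lVert p\rVert^2 = 2c\cdot p + (r^2 -
\lVert c\rVert^2)\) — provides the starting point; Gauss–Newton with
step halving refines it until the relative parameter change falls below
1e-10 (at most 100 iterations; a non-converged fit returns the best
iterate with a warning). Step halving guarantees the refined fit never
has a larger residual sum of squares than its initialisation. Points on
an exact sphere are recovered to machine precision, and the fit is
equivariant under rigid motion and scaling — both properties are
enforced in the test suite.

The *mean error* is the mean absolute orthogonal residual in mm;
*mean error percent* divides by the radius. With radial Gaussian noise
of sd σ the expected mean error is \(\sigma\sqrt{2/\pi}\) (≈ 0.0798 mm
at the scanner's σ = 0.1 mm), which the suite verifies.

Concave/convex classification uses the side of the surface on which the
fitted centre lies relative to the mean vertex normal; facet normals
are oriented outward from the bone (the generator guarantees this; real
meshes may need the orientation file).

Coplanar patches (smallest-to-largest PCA eigenvalue ratio below 1e-10)
cannot identify a sphere; `measure_facet()` then reports the
total-least-squares plane rms instead, with `roc = NA` and a warning.

## Cross-sections, lengths and angles

Cross-sections intersect every triangle with the cutting plane and
chain the segments into polylines; endpoints are keyed by the mesh edge
they lie on, so chaining is exact, and the longest polyline by arc
length is returned (ties broken by lowest starting vertex index;
vertices exactly on the plane are nudged by 1e-12 mm so each crossing
triangle contributes one segment). The inter-facet angle cuts both
facets with the shared mid-coronal plane, fits a total-least-squares
line to each section and reports the angle between them; line
directions are sign-fixed toward +coronal (falling back to +normal for
sections perpendicular to the coronal axis) so the acute/obtuse
character is deterministic. The three-point ROC takes the two endpoints
and the mid-arc-length point of the mid-axial section and returns the
circumradius \(abc/4K\).

## Bicondylar decomposition

The fifth CMC presents two condylar surfaces separated by a ridge
running in the sagittal direction. `partition_bicondylar()` fits this
with an alternating two-sphere scheme: vertices are initialised by the
median coronal coordinate; each sweep fits one sphere per group, then
reassigns vertices; sweeps repeat to a fixed point (or 50 iterations).

The reassignment step deserves a note. A free per-vertex reassignment
to the smaller-residual sphere is the textbook alternating scheme, but
it is *degenerate under scan-level noise*: the flatter sphere can lower
the total objective by capturing the annular rim of the other condyle,
a spatially disconnected solution that has no anatomical reading and
drags the divergence angle and area fractions far from the generating
truth. Because the condyles are coronally contiguous regions separated
by a sagittal ridge, the package instead constrains each reassignment
to the *coronal threshold* minimising the total squared residual (both
sphere-to-side pairings are considered). Each sweep still cannot
increase the objective, convergence is a fixed point of the threshold,
and the result is stable to swapping the initial groups. Manual
condyle outlines can be supplied as per-vertex labels and used either
as an initialisation or, with `iterate = FALSE`, as the final
assignment.

Condyles are labelled radial/ulnar by mean coronal coordinate; faces
take the majority vertex label (ties to radial), and area fractions are
summed face areas over the total. The **angle of divergence** casts a
ray from each sphere centre through its region's area-weighted
centroid, projects both rays onto the mid-coronal plane and reports the
angle between them (`divergence_method = "mean_normal"`, using region
mean normals, is available as an alternative). Two radii within 1% of
each other flag the surface as effectively unicondylar.

## Dorsal flattening

The study's criterion for a flattened dorsal articulation is a
sphere-fit mean error above 0.25 mm. Mean error also rises with scan
noise, so `detect_dorsal_flattening()` combines the threshold with a
geometric check: a plane fitted to the dorsal portion of the vertices
(split by sagittal coordinate) must describe that region better —
smaller rms — than the sphere does. Because the flattened extent is
unknown a priori, the plane-vs-sphere contrast is evaluated over a
ladder of dorsal fractions (0.2 up to `dorsal_fraction`, default 0.5)
and the best contrast reported. Both sub-criteria are returned, so the
bare mean-error rule remains recoverable from the output.

## The synthetic generator

The generator emulates laser-scanned facet patches; its defaults are
the study conditions.

* **Spherical caps** (`generate_cap()`): ring-based geodesic
  triangulation of a cap of given radius (4–21 mm across the published
  envelope) and half-angle, at a target edge length of 0.15 mm.
  The footprint is stretched along the sagittal axis (default
  elongation 1.6) and re-projected onto the sphere, so length exceeds
  width while the curvature ground truth stays exact.
* **Noise**: radial Gaussian displacement along vertex normals with
  sd 0.1 mm, reading the scanner's "±100 µm" as one standard deviation
  of depth error (the error distribution is not otherwise specified).
  Isotropic noise is not modelled.
* **Flattened caps** (`generate_flattened_cap()`): the dorsal fraction
  (default 0.4) of vertices is projected onto the tangent plane at the
  region's centroid. The generator verifies the noise-free best-sphere
  mean error exceeds 0.25 mm, escalating the fraction in 0.05 steps to
  at most 0.8 and erroring otherwise, so emitted fixtures satisfy the
  flattening criterion by construction.
* **Bicondylar patches** (`generate_bicondylar()`): two sphere caps
  over an elliptical footprint, joined at a sagittal ridge; the sphere
  heights are matched at the ridge centre. The ridge position is tuned
  by bisection until the ulnar condyle carries the target share of the
  area (default 30%, within 3 points), and the construction divergence
  is calibrated by fixed-point iteration against the measured
  centre-to-centroid ray angle (to ~0.1°). The grid is anchored at the
  ridge so the split varies continuously during tuning. The ridge blend
  width (`overlap`) is a free parameter defaulting to a sharp ridge;
  the true ridge shape is not quantified anywhere.
* **Cohorts** (`generate_study_cohort()`): per specimen, six facets
  with parameters drawn uniformly from the published cohort ranges;
  fourth-CMC hamate facets are flattened with probability 0.6
  (six-in-ten prevalence). All draws and noise derive from one seed;
  identical seeds give bit-identical output.

What the generator does *not* emulate: registration artifacts between
partial scans, occlusion, surface-powder effects, cartilage thickness,
and real anatomical shape variation beyond sphere/two-sphere geometry.
Passing tests therefore demonstrate the correctness of the measurement
pipeline on surfaces that satisfy the study's geometric model, not the
model's adequacy for real bones.

## Numerical choices and degenerate inputs

* Vertex welding tolerance 1e-9 mm (sews STL triangle soup); faces
  below 1e-12 mm² are dropped; cleaning is idempotent.
* Sphere-fit convergence 1e-10 relative, 100 iterations; coplanarity
  ratio 1e-10; collinearity threshold 1e-12 mm² triangle area.
* Meshes need ≥ 4 vertices after cleaning; a single triangle is
  rejected as unable to support any fit.
* Bicondylar groups must keep ≥ 4 non-coplanar vertices, otherwise a
  degenerate-partition error signals a unicondylar surface.
* Problem sizes in the test-suite and the acceptance script use mesh
  resolutions of 0.18–0.45 mm (a few hundred to a few thousand vertices
  per facet), which the recovery experiments show is ample for the
  published tolerances; the 0.15 mm default matches single-facet
  analysis practice.

## Worked example

```{r example, eval = FALSE}
g <- generate_bicondylar(bicondylar_spec(
  radial_radius = 7.47, ulnar_radius = 8.07, divergence = 10.99,
  ulnar_area_target = 29, noise_sd = 0.1, sense = "convex", seed = 1
))
ori <- orientation_spec(c(1, 0, 0), c(0, 1, 0), source = "landmarks")
frame <- build_frame(g$mesh, ori)
fit <- partition_bicondylar(g$mesh, frame)
glance(fit)
autoplot(fit)
```

## Known limitations

* PCA-derived frames have sign-ambiguous axes; direction-dependent
  outputs need a landmark orientation.
* The divergence angle definition (centre-to-centroid rays in the
  mid-coronal plane) is one of several defensible formalisations; the
  mean-normal alternative is exposed but the two can differ by a few
  degrees on strongly asymmetric condyles.
* The bicondylar model assumes a single sagittal ridge; surfaces with
  more than two condylar regions are outside its scope.
* Cross-sections require the cutting plane to intersect the mesh in at
  least one chained polyline; grazing planes touching isolated vertices
  raise a degenerate-section error rather than guessing.
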
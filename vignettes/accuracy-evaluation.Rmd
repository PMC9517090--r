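---
title: "Evaluating surgical-plan transfer accuracy by surface registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating surgical-plan transfer accuracy by surface registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoicp)
```

## The measurement model

A virtual surgical plan exports a surface model of the skull with the
maxilla in its planned position (T0). A postoperative CBCT scan, segmented
to a surface, shows where the maxilla actually ended up (T1). The two
models live in unrelated scanner coordinate frames, so "how far is the
achieved maxilla from the planned one" is only meaningful after the frames
are reconciled — and the reconciliation must not use the maxilla itself,
which is exactly the part that moved.

The package therefore separates two regions, both defined on T0:

* **ROI1** — a reference region untouched by surgery (orbital frames,
  frontal and zygomatic bones). It is the anchor: any residual mismatch
  here is scan/segmentation error, not surgery.
* **ROI2** — the mobilised maxilla between the Le Fort I osteotomy and the
  necks of the teeth. It is measured, never used for alignment.

The pipeline estimates a single rigid transform (rotation $R$,
translation $t$) from the T1 ROI1 points onto the T0 ROI1 surface and
applies it to the *whole* T1 mesh; the displacement that remains in ROI2
afterwards is attributed to the surgical transfer. The per-vertex
point-to-surface distances $d_i$ over ROI2 are summarised as
$\mathrm{RMS} = \sqrt{\tfrac1n\sum_i d_i^2}$ — the case's *3D error* —
plus the maximum, minimum and mean deviation. RMS at or below 2&nbsp;mm is
reported as clinically acceptable; the band is symmetric and the boundary
inclusive.

Assumptions worth stating explicitly: the cranial reference really is
rigid between scans (true for bone over weeks); scale is preserved
(surgery does not rescale the skull, so similarity/affine registration is
deliberately out of scope); and one rigid transform describes the maxilla's
error (a segmental osteotomy violates this within ROI2 — see Limitations).

## Registration

**Initial alignment** matches centroids and principal axes of the two ROI1
point clouds. Axes come from the covariance eigenvectors in descending
eigenvalue order; since eigenvectors are sign-ambiguous, the four
proper-rotation sign assignments are scored by nearest-neighbour RMS and
the best kept. This lands within a few degrees even for pose offsets far
beyond the ICP convergence basin (a 170° test case is part of the suite).
If any two adjacent eigenvalues are within a factor 1.05 the axes are
ill-defined and the method falls back, with a warning, to centroid-only
alignment.

**Optimized alignment** is trimmed point-to-mesh ICP. Per iteration:

1. every (transformed) source point is matched to its exact closest point
   on the target surface — point-to-triangle projection, not
   vertex-to-vertex, so differing tessellations of the two scans do not
   bias the fit;
2. pairs beyond `max_correspondence_distance` are rejected and the worst
   `trim_fraction` of the remainder dropped (robustness against fixation
   plates and metal scatter overlaying the postoperative surface);
3. the closed-form weighted Kabsch/SVD solution is computed on the
   survivors and composed onto the running transform. A reflection, which
   the SVD can return for pathological configurations, is repaired by
   flipping the smallest singular vector so $\det R = +1$.

Iteration stops when the RMS over surviving pairs changes by less than
`rms_change_tolerance` or at `max_iterations`. With unbounded
correspondence distance the recorded RMS sequence is non-increasing after
the first re-correspondence (each step can only shorten matched distances,
the trim keeps the best fraction, and the fit minimises over a set
containing the previous transform); the suite asserts this on every run.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `max_iterations` | 100 | – | identity-init convergence on smooth surfaces is linear; after PCA initialisation a handful suffice |
| `rms_change_tolerance` | 1e-5 | mm | far below scanner resolution (0.3 mm voxels) |
| `trim_fraction` | 0.1 | – | tolerates ~10 % corrupted surface (plate overlay) without biasing a clean fit noticeably |
| `max_correspondence_distance` | Inf | mm | the trim already handles outliers; a gate is available for partial overlaps |
| `sample_count` | all | – | ROI1 point counts here are small; subsampling (seeded) exists for dense clinical meshes |
| acceptability threshold | 2 | mm | the clinical band used across the orthognathic-accuracy literature |

Classic point-to-point-correspondence ICP converges slowly in the tangential
directions on smooth surfaces: from an identity initialisation the
reference-dome tests need hundreds of iterations to pass 0.05°. That is why
the pipeline always runs the PCA initial alignment first — after it, ICP is
a short polish — and why `icp_refine()` exposes the iteration cap rather
than hiding it.

## Numerical choices

* **Closest-point queries.** Exact region-based point-to-triangle
  projection in C++, brute force over faces with axis-aligned-bounding-box
  pruning (seeded by the nearest face centroid). Ties in distance resolve
  to the lowest face index — reproducibility over micro-optimisation — and
  the pruned path is tested to agree with the unpruned scan exactly. The
  box-pruning test is a *strict* inequality: an equal-distance face must
  still be examined or the tie-break would depend on the pruning order.
* **Signed deviations.** Sign is taken from the face normal at the closest
  point; zero distance counts positive. Signed mode refuses meshes whose
  winding is inconsistent (a shared edge traversed twice in the same
  direction), because the sign field would be meaningless; unsigned mode
  is always available. The headline RMS uses **unsigned** distances: the
  3D error is a magnitude and the ±2 mm band is symmetric. Signed fields
  exist for the colormap and the min/max deviation report.
* **Acceptability boundary.** `rms <= threshold` with a fixed numeric
  slack of 1e-9 mm, so that a case engineered to sit exactly on the
  boundary is not classified by ~1e-14 mm of floating-point registration
  residue. The slack is six orders of magnitude below voxel size.
* **Vertex merging on STL import** uses a 1e-6 mm tolerance: STL stores
  every facet's vertices independently and they must be re-unified, but
  1e-6 mm is far below any real geometry spacing. STL is unitless;
  coordinates are interpreted as millimetres throughout.
* **Degenerate input.** `validate_mesh()` removes zero-area and
  repeated-index faces (and then unreferenced vertices) and is idempotent;
  geometry routines refuse unvalidated degenerate faces rather than
  guessing.

## The phantom generator

`generate_phantom_pair()` builds the study's conditions synthetically so
that every stage has known ground truth:

* **Geometry.** The cranial reference is a half-ellipsoid dome, semi-axes
  (70, 90, 60) mm, carrying three fixed surface bumps (two anterior
  "orbital", one right "zygomatic"). The shape is schematic on purpose —
  the validation currency is parameter recovery, not anatomy — but it is
  deliberately anisotropic and asymmetric: a true hemisphere has a
  rotational symmetry axis about which no landmark-free registration could
  recover a rotation, and 180° ambiguities would defeat the PCA sign
  search. The maxillary body is a detached ellipsoid (22, 16, 12) mm below
  the anterior dome, or a flat square patch for analytic checks.
* **Truth.** T1 is T0 with the maxilla displaced by a known rigid residual
  (acting about the maxilla centroid), the whole mesh moved by a known
  scan-frame pose, then isotropic Gaussian vertex noise (optionally along
  normals), optional tangential "remeshing" jitter, and optional
  plate/metal artifacts: a fraction of maxillary vertices pushed 2–5 mm
  outward along their normals. All randomness flows from one seed; two
  calls with the same spec are bitwise identical.
* **The flat patch is the analytic anchor:** displacing it by a pure
  normal translation $t$ puts every vertex at exactly distance $t$ from
  the original plane, so the pipeline must report RMS $= t$ to 1e-6 mm —
  no oracle needed beyond arithmetic.
* **What it does not emulate:** CBCT physics, segmentation error
  structure, dental anatomy, and multi-fragment (segmental) maxillas — the
  segmental subgroup exists as a label only, the ROI2 body always moves as
  one rigid piece. Passing phantoms therefore demonstrates correctness of
  the measurement chain, not clinical performance on real scans.

`generate_cohort()` emulates the two-arm study: per group it draws
per-case displacement magnitudes around the group's target mean 3D error
(defaults 1.22 and 1.63 mm, the published group-level errors of the
splintless and splint arms, with 0.4 mm between-patient SD — the
literature gives no per-patient magnitudes, so the group means are used as
plausible anchors). Two choices make the cohort realise its nominal
conditions exactly rather than approximately:

1. the drawn magnitudes are standardised within each group to the target
   sample mean and SD (with five cases per arm, raw draws would wander by
   ±0.18 mm SE — the cohort would then test the random number generator,
   not the pipeline);
2. each magnitude is calibrated against the T0 geometry (secant solve on
   the zero-noise deviation RMS of the translated maxilla), because for a
   curved body the RMS of a translation by $m$ is slightly below $m$.

Subgroup labels follow a 3 monobloc + 2 segmental split per arm. Cohorts
written to disk use *predicate* ROI files (half-space for the dome, sphere
for the maxilla): STL re-import merges per-facet vertices and renumbers
them, so index lists would not survive the round trip.

## Statistics

Case-level error is the arithmetic mean over operators
(`average_operators()`; replicate runs with jittered ROI boundaries stand
in for operators repeating the manual selection). Group summaries use the
sample SD ($n-1$). Normality is checked with the Lilliefors variant of the
Kolmogorov–Smirnov test (`nortest::lillie.test`) — the reference normal's
parameters must be estimated from the data, and the plug-in correction is
what keeps the test honestly sized.

The two-group comparison defaults to the **independent pooled t-test**.
The clinical protocol this package mirrors describes a "coupled samples"
(paired) test, but its two arms contain different patients; pairing across
unrelated individuals is undefined, so the package defaults to the
independent test and emits a warning noting the substitution. Paired and
Welch modes are available for designs that need them. Degenerate inputs
follow fixed conventions: zero spread with equal means gives $p = 1$, a
constant non-zero shift gives $p = 0$. Significance is $p < 0.05$ by
default; no multiplicity correction is applied across the three contrasts
(overall, monobloc, segmental), matching the reporting structure it
mirrors.

## Problem sizes and verification

The shipped validation (test suite and `scripts/acceptance.R`) uses dome
tessellations of 433 vertices / 828 faces and maxilla bodies of 266
vertices / 528 faces — small enough that the whole suite runs in seconds,
dense enough that registration errors are resolution-limited well below
the tolerances asserted: pose recovery over 20 random scan frames
(rotations ≤ 30°, translations ≤ 20 mm) is exact to ~1e-6° at zero noise
and ~0.06° / 0.03 mm at 0.1 mm noise; the 10-case cohort recovers its
group means to a few thousandths of a millimetre. The acceptance script
recomputes all of these from its `--seed` at run time; no reported number
is stored anywhere.

## Known limitations

* Direction of measurement is achieved-vs-planned (T1 ROI2 vertices
  against the T0 ROI2 surface), not a symmetric Hausdorff distance; the
  reverse direction is a matter of swapping the meshes in the config.
* The method reports the *magnitude* of the transfer error only. By
  construction it cannot attribute the error to rotations/translations
  about specific axes; tools needing that decomposition should fit the
  residual transform instead.
* Face winding is trusted as read; there is no global re-orientation pass.
  Inconsistent winding is detected and blocks signed mode only.
* ROI definitions resolved on T0 are applied by index to T1, which
  presumes shared vertex ordering (true for phantom pairs and
  template-derived exports); `roi1_t1` overrides this for independently
  meshed scans.
* Voxel-based comparison, DICOM ingestion, segmentation and mesh repair
  beyond degenerate-face removal are out of scope.
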
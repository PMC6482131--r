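---
title: "Quantifying thoracic aortic dilatation between serial CTA scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thoracic aortic dilatation between serial CTA scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Aneurysm surveillance decisions rest on the maximal cross-sectional diameter
of the aorta, measured in a plane perpendicular to the vessel axis, and on
how much that diameter has grown since the previous scan.  Measuring growth
manually means re-deriving double-oblique planes at seven standardized
landmarks (sinotubular junction, mid ascending aorta, proximal arch, mid
arch, proximal descending aorta, mid descending aorta, diaphragm) on *both*
scans — slow, and a source of inter-observer variability precisely where
millimetres matter (a 5 mm increase is clinically actionable).

`aortrack` automates everything after a single set of landmark clicks on the
baseline scan:

1. **Baseline centerline** — wave-propagation shortest path through the
   contrast-filled lumen, then recentring to the medial axis.
2. **Baseline surface** — a deformable Loop-subdivision tube fitted to the
   gradient ridge of the lumen edge.
3. **Alignment** — rigid, then affine registration of the follow-up scan by
   mutual-information maximization with stochastic gradient ascent, masked
   to the bounding box of the segmented baseline aorta.
4. **Follow-up surface** — the baseline surface deformed onto the aligned
   follow-up scan after centerline-based adaptive thresholding.
5. **Measurement** — the *same* baseline-defined planes cut both surfaces;
   maximal diameters, differences, diameter-vs-arc-length curves and a
   per-ring dilatation field are reported.

Because both surfaces are measured with identical planes in the baseline
frame, plane-selection variability cancels out of the longitudinal
difference.

## Models and algorithmic choices

### Lumen intensity model and centerline

Lumen intensities around a user seed are summarized by a Gaussian (mean m,
SD s, floored at 1 HU).  Each voxel gets the shifted negative log-likelihood
cost `((I - m)/s)^2 / 2`; voxels beyond a 3-sigma admissibility ceiling are
blocked.  The centerline is the Dijkstra shortest path on the 26-connected
grid with edge weight `(mean endpoint cost + lambda) * step length`.  The
small additive length penalty `lambda` (0.05/mm) matters: inside homogeneous
contrast the likelihood cost is nearly zero and *every* route ties, so
without it the returned path is arbitrary.  With it, ties break toward the
shortest admissible route.  Shortest paths hug the inner curve of bends, so
each point is then moved to the area-weighted intensity centroid of the
admissible lumen in its normal plane (8 passes, 20 mm search radius) and the
curve is resampled at 1 mm with 5-point moving-average smoothing.

Endpoint detection is best effort and deliberately overridable (the
semi-automatic contract): the descending endpoint is tracked from the most
caudal admissible in-plane component, the aortic-root endpoint from the
separate ascending component, in both cases taking the most caudal slice at
which the tracked component reaches ~95% of its full caliber — rounded
partial-volume end caps taper below that.

### Deformable subdivision surface

The control mesh is a tube of rings (2 per cm, 16 vertices each) placed with
rotation-minimizing frames so adjacent rings are untwisted.  Loop
subdivision (2 levels, cubic B-spline rules on the two open boundary loops)
yields the measurement surface.  The refined surface of a K-gon ring cage
contracts radially by a factor of about `(2 + cos(2*pi/K))/3`; the package
inflates refined vertices about the interpolated ring axis by the inverse
factor ("cage-to-surface calibration") so the measured surface passes
through the fitted cage.  Without this, every diameter would carry a -2.5%
bias at K = 16.

Fitting deforms control vertices along their outward normals toward ridges
of the Gaussian-smoothed gradient magnitude (sigma defaults to 1.4x the
voxel size — below one voxel the trilinearly sampled ridge locks to voxel
centres).  The accepted ridge is the *first* local maximum, scanning
outward, that exceeds 30% of the ray maximum: this lands on the inner
lumen-wall edge ("inner edge to inner edge") rather than on the outer wall,
and it keeps a nearby bright structure such as bone — whose edge gradient
can be nearly three times the lumen edge's — from capturing the vertex.
Displacements are relaxed (factor 0.5), refined to sub-sample precision by
a parabolic fit through the ridge samples, and Laplacian-smoothed over the
ring/angular neighbours (weight 0.3, 8 passes per iteration; the passes
widen the smoothing support and suppress voxel-phase wiggle that the
max-chord diameter statistic would otherwise amplify).  Iteration stops when
the largest displacement falls below 0.05 mm, with a 200-iteration cap.
With smoothing weight 0 the vertex move is restricted to the best sampled
point between the current position and the target, which makes the
vertex-summed cost exactly non-decreasing — the property the test suite
asserts.

The follow-up fit starts from the fitted baseline mesh with a narrower
search range (6 mm vs 10 mm): after alignment, only dilatation remains.
Before it, centerline-based adaptive thresholding clamps each 20 mm
arc-length slab to `[m - 4*s_slab, m + 2*s_lumen]`.  The upper bound uses
the *local lumen* SD, so bone just above the lumen range is flattened to
roughly lumen + 20 HU; the lower bound uses the *whole-slab* SD, which is
large, so it falls below the background and the lumen-background edge
itself is untouched.  A single symmetric-SD clamp cannot do both jobs at
once.

### Registration

Mutual information (32 bins, in nats) is estimated from samples drawn
uniformly in the fixed-image mask — the bounding box of the baseline
segmentation plus 10 mm, which keeps the rib cage from dominating the
metric.  Optimization is stochastic gradient ascent (central finite
differences with common random samples, normalized gradient, gain decaying
as `(t + 20)^-0.6`) over a 3-level pyramid (4x/2x/1x with matched Gaussian
smoothing), 6 rigid parameters about the mask centroid, then 12 affine
parameters, followed by a deterministic Nelder-Mead polish on a fixed
32 768-point sample set.  Polish samples are jittered uniformly inside
their voxels: with pure voxel-centre sampling the linearly interpolated MI
landscape carries grid-phase ripples that bias the optimum by a
half-voxel.  All randomness flows from the config seed, so results are
bit-reproducible.

Two design points deserve emphasis:

* **The affine stage excludes the lumen interior.**  On a follow-up scan
  whose aorta has genuinely dilated, an unconstrained affine registration
  *prefers* absorbing the dilatation as scaling — we measured higher MI at
  the absorbing optimum than at the true transform.  The affine metric
  therefore masks out everything within the fitted baseline radius plus
  6 mm, anchoring the refinement to stable anatomy (spine, sternum, ribs,
  soft tissue).  The rigid stage, which cannot absorb dilatation, uses the
  plain bounding-box mask.
* **Affine never degrades the rigid result**: if the refined transform has
  lower MI than its initialization on a common deterministic sample set,
  the initialization is returned.

The follow-up volume is resampled onto the baseline grid exactly once,
after the composite transform is known, to avoid double interpolation blur.

### Measurement

A landmark annotation is projected to its nearest centerline position; the
measurement plane passes through that position with the tangent as normal.
The plane-mesh intersection is assembled into closed loops from the
per-triangle crossing segments; the loop nearest the landmark is kept, and
its maximal diameter is the diameter of the polygon vertex set (convex hull
+ pairwise maximum — exactly the brute-force answer).  Planes that would
fall within 10 mm of the open tube ends are nudged inward along the
centerline, because a plane clipping a boundary ring yields an open loop
rather than a contour; for the near-cylindrical aorta the induced diameter
change is a few hundredths of a millimetre.  The dilatation field assigns
each baseline ring the follow-up-minus-baseline ring diameter, matched by
arc length, and is exported as a per-vertex scalar (PLY `quality` channel /
VTK `dilatation_mm`), the 3-D color-coded overview of where the aorta grew.

Agreement statistics use Bland-Altman differences (SD with n-1, limits
mean +/- 1.96 SD) and ICC(A,1) — two-way, absolute agreement, single
measure — computed from the standard mean-squares decomposition.  Absolute
agreement is the right variant here because two observers' diameters must
be interchangeable in absolute millimetres, not merely correlated.  The
variant is fixed and printed; with only two raters and small batches the
ICC is reported alongside the raw differences rather than instead of them.

## The synthetic phantom: what it does and does not emulate

No patient data ship with the package, so validation rests on a candy-cane
phantom with exact ground truth: ascending limb (60 mm), semicircular arch
(radius 35 mm), descending limb (110 mm); lumen radius tapering 16 to 12 mm
along the arc; 2 mm wall; lumen 300 HU, wall 60 HU, background 20 HU, bone
700 HU; 0.6 mm partial-volume blur; additive Gaussian noise (SD 10 HU)
under a fixed seed.  Seven landmarks sit at fixed arc positions spanning
all segments.  The follow-up twin adds a known radius increment profile and
maps the whole scene by a known rigid transform before rasterization, so
every derived quantity has an analytic reference.

The scene also contains stable "anatomy": a vertebra-like bone column
posterior to the descending aorta, a sternum-like anterior chain, rib-like
lateral spheres, and a smooth correlated soft-tissue texture (SD 35 HU,
8 mm correlation length) that is *fixed in scene coordinates* — both time
points share it, transformed with the scene, exactly as patient anatomy is.
This matters: with a featureless background the affine registration problem
is ill-posed in the presence of dilatation (see above), which no optimizer
can fix; the texture and bones restore the anchoring that real thoraces
provide.

Not emulated: calcification and thrombus texture, dissection lumina, ECG
phase motion, supra-aortic branch take-offs by default (a three-branch flag
exists for the region-growing QC overlay), beam hardening, and the full
richness of soft-tissue contrast.  Passing the phantom suite therefore
demonstrates correctness of the geometry, optimization and statistics
chain under controlled conditions — not clinical robustness to pathology
or artifacts, which requires patient data.

## Test problem sizes and numerical tolerances

The validation suite runs phantoms at 1.4 mm isotropic voxels (its standard
working grid) with one finer 0.7 mm series for the centerline accuracy
checks; registration uses 150-200 iterations per level and 2 048 samples
per iteration.  These sizes were chosen once as a balance between fidelity
and runtime of a routine test cycle.  Key asserted properties:

* centerline within 1.5 mm (mean) of truth on noisy 0.7 mm phantoms;
* fitted ring radius within half a voxel of truth at >= 95% of rings
  (noiseless), mean error < 0.5 mm at default noise;
* recovered registration within 1 degree / 1 mm / 1% scale for rigid +
  scale misalignments up to 10 degrees / 10 mm / 5%, including a 30 mm
  capture-range case, deterministic per seed;
* all seven landmark diameter differences within 1 mm of analytic truth
  end-to-end, under uniform (+3 mm radius) and localized (+5 mm over 40 mm
  of arc) dilation with rigid repositioning;
* +/- 3 mm landmark-annotation jitter changes per-landmark mean differences
  by <= 1 mm with ICC >= 0.95 between jittered and unjittered batches;
* null-change control (follow-up = baseline): all differences < 0.5 mm.

Degenerate inputs are handled explicitly: zero-variance ICC input, single
admissible voxels in region growing, planes beyond the tube, collinear
polygons, coincident path endpoints, insufficient registration overlap, and
meshes leaving the volume all raise descriptive errors rather than
returning numbers.

## Known limitations

* The end rings of the tube surface are less constrained than the interior;
  measurement planes are kept 10 mm from the open ends.
* The maximal diameter is the polygon diameter of the cross-section; for
  strongly non-convex sections (dissection) this overestimates the lumen
  caliber — out of scope here.
* Affine scale is identifiable only to about 1% on the phantom (and, we
  expect, on patient data): the MI landscape is nearly flat along scale
  directions that move in-mask structure by fractions of a voxel.
* The adaptive threshold assumes the lumen is the brightest *large*
  structure near the centerline; densely calcified walls adjacent to the
  lumen would be clamped less aggressively than ideal.
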
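---
title: "Simulating cortical bone fractures from 2D patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cortical bone fractures from 2D patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortifrac)
```

## The model

`cortifrac` treats a diaphyseal fracture as a geometric object with two
faces: a compact 2D description — polylines on the unwrapped bone surface,
one set per cortical layer — and its 3D realization on a particular bone
mesh. The package maps between the two in both directions: a pattern can
be projected onto any intact bone and the mesh actually fragmented, and a
fractured fragment mesh can be reduced back to a pattern. This decouples
fracture morphology from bone anatomy: one validated pattern generates
plausible fractures on bones of different size and shape, and two
fractures can be compared through their patterns and height maps rather
than through raw meshes.

Several assumptions are built in, and they bound the scope:

* bones are **elongated** with a well-defined long axis, so a cylindrical
  unwrap (`x = theta * R`, `y` = axial height) is a faithful chart of the
  working band. Strongly curved or articular geometry is out of scope.
* the cortex is a **two-layer shell**: an outer and an inner surface,
  radially ordered along every ray from the axis. The medullary canal is
  hollow and must stay unmeshed.
* fractures are **through-thickness**: every fracture line is (or closes
  into) a loop that separates the shell locally into two sides. Partial
  cracks, crush defects and impacted regions are not modelled.

## Coordinates and conventions

All coordinates are millimetres — STL/PLY/OBJ carry no units, so mm is
asserted by convention. The bone axis is the first principal direction of
the vertex cloud (sign toward +Z); axial *heights* are measured from the
low end of the bone, so a 100 mm shaft spans heights 0–100. Pattern
coordinates are `(u, v)` with `u` in `[0, 1)` the normalized
circumferential position (`u = 0` an arbitrary but persisted reference
meridian, all wrap arithmetic modulo 1) and `v` in mm. `u` is rescaled to
arc length at projection time, which is what makes patterns
bone-independent transversally; `v` stays metric because fracture extent
along the shaft is an anatomical quantity, not a proportion.

Both cortical layers are unwrapped in the *same* frame (the outer-radius
cylinder). The layers remain independent — separate lines, separate cut
points — but share a coordinate system, which keeps outer and inner
contours of one interface comparable. The inner layer's own radius would
be an equally defensible frame; the shared frame was chosen so that the
inner/outer offset of a fracture line is visible in the coordinates
themselves rather than hidden in a second scale factor.

## The synthetic generator as study population

`generate_long_bone()` builds a watertight two-layer shell: outer tube,
inner tube at `outer_radius - thickness`, closed by annular caps
(labelled as outer cortex; diaphyseal fractures never touch them).
Radius and thickness accept piecewise-linear axial profiles; a `curvature`
parameter bows the shaft; `perturb_surface_noise()` adds a smooth,
seeded, radially bounded sinusoidal field applied identically to both
layers, so layer ordering and local thickness are preserved exactly and
the field vanishes at the shaft ends.

Default study conditions used throughout the tests: length 100 mm, outer
radius 10 mm, cortical thickness 3 mm — a mid-shaft femur-like tube — at
`n_theta = 64`, `n_z = 32` (about 1 mm circumferential and 3 mm axial
resolution), with `n_theta = 128`, `n_z = 48` where round-trip fidelity is
measured. What the generator does *not* emulate: condyles and epiphyses,
anisotropic cortical thinning, trabecular interior, segmentation noise and
topological defects of real CT meshes. Tests passing on these fixtures
therefore demonstrate the geometric correctness of the pipeline, not
robustness to imaging artefacts.

## Patterns

`generate_parametric_pattern()` encodes the AO/OTA diaphyseal classes as
closed loops:

* **transverse** — one constant-height loop, optional sinusoidal waviness
  (integer wave count keeps it closed);
* **oblique** — a wrap-symmetric tent: height rises at slope
  `tan(angle)` in arc length over half the circumference and falls over
  the other half, so the loop closes and its total rise-and-fall over one
  wrap is `C * tan(angle)`. A constant-slope line over a full wrap cannot
  close (it is a helix), so the tent is the closed-curve realization of
  "an oblique cut at angle alpha";
* **spiral** — a helix of exactly one full turn plus a meridian hinge
  segment back to the start. With one turn the hinge meets the helix only
  at its endpoints; more turns would self-intersect a single hinge, so the
  axial advance (`pitch`) is the free parameter. The hinge meridian
  defaults to `u = 0.37`, away from the `u = 0` seam;
* **wedge** — the main transverse loop plus a closed triangular loop just
  above it (the butterfly fragment). Detached fragments are encoded as
  loops, never as line junctions: every line is then one fracture
  interface between exactly two fragments, which is what makes the
  volume-conservation argument below exact;
* **comminuted** — the main loop plus `k >= 2` polygonal loops in
  distinct circumferential slots with seeded jitter. Loop sizes default to
  several mesh cells across; a detached region smaller than the local
  triangle size is not representable on that mesh, whatever the cutter
  does.

Inner-layer lines are the outer lines shifted by `inner_offset` plus
smooth periodic noise bounded by `inner_noise` (periodic in normalized arc
position, so closed loops stay closed) — the fracture front shifts as it
traverses the cortical thickness, and this is the simplest deterministic
model of that shift with a controllable magnitude.

`validate_pattern()` measures line count, total length in circumference
multiples, enclosed region count (by rasterized flood fill of the
periodic band, 256 cells per axis) and longitudinal extent against
editable per-type criteria shipped in
`inst/extdata/forensic_criteria.json`. The published sources for such
criteria give the three measured aspects but not the numeric thresholds,
so the defaults here are chosen to accept the package's own parametric
output and reject class mismatches; users with access to forensic case
statistics should edit the file.

## Projection and cutting

The projection cylinder radius is the *generalized radius*: the mean
distance to the axis of outer-cortical vertices in an axial band around
the fracture height (band half-width adapted to the mesh's axial
resolution so at least one vertex ring contributes). Placement scales `u`
by `2 * pi * R`, centres the pattern's longitudinal midrange at the
fracture height, and — when the pattern records the circumference it was
designed or extracted at — fails with a *scale-infeasible* error if the
implied transverse stretch exceeds `aspect_limit` (default 2). This is
the mechanism by which a pattern taken from a large bone refuses a much
thinner one instead of producing a distorted fracture.

Cut points are computed per layer as pattern-segment × mesh-edge
intersections in the unwrapped plane, deduplicated per undirected edge
(across the two incident faces and across seam copies; faces crossing the
seam are tested against the pattern shifted by ±C). Crossings within
`snap_tolerance` of an endpoint are flagged `on_vertex` and merged per
vertex — flagged only; the decision to snap belongs to the cutting
strategy, so strategy choice lives in one place. Consecutive cut points
along a polyline are paired through their shared face; when a near-tangent
crossing is lost to floating-point degeneracy, the pair is routed through
the shared vertex of the two cut edges, which is the limit geometry of the
missed crossing.

The three cutting strategies are one mechanism: snap a cut point to its
edge's nearest endpoint iff `min(t, 1 - t) <= threshold`.
`subdivision` is threshold 0 (only exact vertex hits snap — a zero-length
edge piece cannot be subdivided), `approximation` is threshold 0.5, and
`hybrid` defaults to 0.10 — the snapping band expressed as a fraction of
the cut edge, which makes it scale-invariant. The limit identities
(hybrid(0) = subdivision, hybrid(0.5) = approximation, face for face) hold
by construction and are verified over 100 random fixtures anyway, as a
guard against the mechanism drifting apart in future changes.

Faces are rebuilt by splitting their polygon along each fracture chord
and triangulating every piece with a small dynamic programme that
minimizes the mean quality ratio `q = R / (2r)` (circumradius over twice
the inradius: exactly 1 for equilateral triangles by Euler's inequality,
growing without bound with degeneracy; values up to about 1.3 are
conventionally "acceptable"). Lower mean q is better; the hybrid strategy
exists precisely because subdividing near a vertex manufactures slivers
with enormous q, and the test suite checks statistically that
hybrid(0.10) achieves a lower mean q than pure subdivision. Surface area
is conserved exactly by all strategies (the same polygons are
re-triangulated; approximation changes no geometry at all). Under
approximation, a crossing pair collapsing onto one shared vertex is
accepted — the fracture path continues through the vertex, and an edge
traversed out-and-back by a collapsed sliver is removed by a mod-2
reduction per line and layer.

Fragments: surface regions are grown over face adjacency without crossing
fracture edges (connected components, so the result cannot depend on seed
choice). A detached wedge appears as *two* surface patches — its outer and
inner cortical faces — that belong to one solid; patches are grouped into
solids by majority vote of their face centroids against the rasterized
planar regions of the placed pattern. The fragment count therefore equals
the pattern's region count, by construction of the vote.

## The fracture wall

Each pattern line yields one interface with an outer and an inner contour
loop (fracture edges chained per layer; inner winding aligned to the
outer's). The annular wall between them is triangulated as two arc-length
zipper ribbons through an intermediate mid-thickness ring of new vertices,
followed by constrained Lawson (max-min-angle) edge flips — the flip
criterion that characterizes the constrained Delaunay triangulation in the
planar case, and remains well defined for the non-planar spiral contours
where any single projection plane would degenerate. The contour loops are
constraint edges and survive to the wall boundary unchanged; flips may
never create a diagonal joining two vertices of the same loop (it could
coincide with a shell edge or fold the wall flat). Only the ribbon between
the loops is ever meshed, so the medullary canal stays hollow without an
explicit hole test.

Roughness, two methods, displacements drawn uniformly from `[-tau, tau]`
(signed and symmetric; `one_sided = TRUE` gives `[0, tau]`), `tau` in
0.1–1.0 mm:

* **pre-triangulation**: the mid-thickness ring vertices are displaced
  along the local wall normal before the ribbons are built, with halving
  retries (at most 5) for displacements that would degenerate the wall.
  The contour loops stay fixed. Displacing the contours themselves would
  drag the shells of *both* mating fragments and change the union volume
  at first order — incompatible with exact conservation — so the interior
  ring is the fracture-zone vertex set this method perturbs.
* **post-triangulation**: each wall triangle is replaced by three
  triangles fanning from its centroid displaced along the face normal.
  Triangle count exactly triples; the boundary is untouched. At
  `tau = 0` the two methods coincide up to the centroid refinement (the
  post method's vertex set contains the pre method's).

One root seed drives everything; each interface derives a child seed from
the root and the pattern-line index, so results do not depend on the order
in which interfaces are processed.

**Why volume conservation is exact.** Each interface wall is triangulated
once and attached to its two fragments with opposite orientations (the
orientation is fixed per fragment by requiring each shared edge to be
traversed in opposite directions, the closed-orientable-mesh condition).
In the sum of signed fragment volumes every wall contributes twice with
opposite signs and cancels, leaving exactly the intact shell's shell
faces — so the sum equals the intact volume up to float summation,
regardless of pattern, strategy, or perturbation. The test matrix (5
pattern types × 3 strategies × 3 perturbation configurations) verifies
this at 1e-9 relative together with watertightness of every fragment.

## Pattern recovery and height-map validation

`detect_fracture_zone()` needs no labels: the fragment's principal-axis
bounding box is discretized into a cross-section grid (default 20 cells
per axis, about one mesh cell at the default resolutions) swept parallel
to the long axis. The axis comes from the area-weighted covariance of
face *normals* (smallest eigenvector) rather than vertex PCA — a tube's
wall normals span the cross-plane exactly, while vertex PCA tilts on
fragments with slanted fracture ends — and the cross-section is recentred
by an algebraic circle fit, since the vertex centroid of an asymmetric
fragment sits off-axis. Per grid column the extremal vertex along the
sweep is a candidate, classified outer/inner by radial distance relative
to the fitted radii; candidates far below their angular neighbours
(quantile-robust tolerance) are grid artefacts and dropped. An end whose
remaining candidates show less than `min_relief` (default 0.1 mm) of
axial relief is a flat machined end, not a fracture: this is how an
intact shaft returns an empty zone even though its cap rims are genuine
90-degree creases. The honest corollary: a perfectly flat, unperturbed
transverse fracture end is geometrically indistinguishable from a cap and
must be selected with `end = "+"`/`"-"` explicitly.

`extract_pattern()` maps zone points through a cylinder frame to
`(u, v)`, chains each layer by wrap-aware nearest neighbour (trailing
stragglers trimmed; an early long jump is a genuine branching ambiguity
and errors), simplifies with Douglas–Peucker (default 0.3 mm) and closes
the loop when the chain returns to its start. Round-trip fidelity
(generate → fracture → detect → extract) is bounded by mesh resolution
and improves monotonically with it; at `n_theta = 128` the symmetric
Hausdorff distance to the generating line is well under 1.5 mean edge
lengths.

Height maps place a reference plane perpendicular to the axis `margin` mm
above the highest fracture-zone point and record perpendicular distances
down to every point. Means are margin-sensitive, so reports carry the
margin and comparisons require equal margins. The comparison report
implements the thickness-ratio scaling
`MMAS_scaled = MMAS * T_original / T_new` with T the generalized radius
at the fracture height, and the sign conventions
`distance = MMAS_scaled - MMAR`,
`percent = (MMAR - MMAS_scaled) / MMAR * 100`. The operational content of
the scaling is the compensation identity: fracturing a uniformly
`s`-scaled copy of a bone (same pattern scaled by `s`, same seeds) and
rescaling its mean map by the measured radius ratio reproduces the
original's mean map. The acceptance suite verifies this at 1.4× to ~1e-15
relative, with perturbation off and margin 0 — a fixed absolute `tau` and
a fixed margin are deliberately *not* scaled with the bone, so the
identity is exact only without them.

## Numerical choices and limitations

* Degenerate-face tolerance 1e-10 mm²; intersection degeneracy floor
  1e-12 on the orientation determinant; edge-parameter deduplication at
  1e-7; exact-vertex snap floor 1e-9.
* Intersection tests are floating-point with inclusive boundary handling
  and vertex merging, not exact arithmetic. Patterns aligned exactly with
  mesh lattices (a transverse cut on a vertex ring) are handled through
  the vertex-merge path and are exercised by the tests, but adversarial
  exact-degeneracy inputs can still defeat the recovery; the failure mode
  is a clear pairing or closure error, never a silently wrong mesh.
* A face may carry several fracture chords only if they share a vertex or
  nest without crossing; genuinely crossing chords (pattern features
  below mesh resolution) raise a refinement request.
* `pattern_regions()` is rasterized (256² cells): regions thinner than a
  cell can merge. Pattern features are expected to span several mesh
  cells and raster cells alike.
* Quality after cutting is optimized only locally (per face polygon, and
  Lawson flips on the wall); no global remeshing.
* Fracture walls connect radially corresponding contour points by
  arc-length correspondence; for extreme inner/outer line offsets
  (approaching the band height) the correspondence can shear the wall.

## Problem sizes in the test suite

Unit and property tests run on 16–64-segment tubes; the conservation
matrix uses the default 64 × 32 tube (45 pipeline runs); round-trip
extraction uses 128 × 48. The full suite and the acceptance script each
complete in a few minutes on one CPU; these sizes were chosen as the
smallest at which discretization-dependent bounds (volume within 1% of
the analytic shell, Hausdorff under 1.5 edge lengths) are comfortably
diagnostic.
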
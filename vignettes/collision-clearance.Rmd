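---
title: "Collision clearance simulation: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collision clearance simulation: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linacclear)
```

## What is being modeled

A C-arm linac delivering noncoplanar arcs is simulated as rigid geometry. The
patient body contour, couch, and immobilization structures are triangle meshes
fixed in the DICOM patient frame (+x patient-left, +y patient-posterior,
+z patient-superior, origin at the plan isocenter). The gantry head is the
single moving body: for each beam, the head mesh is posed by the composition

```
pose(gantry, couch, collimator, shift) =
    T(shift) . R_y(-couch about room-vertical) . R_z(gantry) . R_y(collimator)
```

applied to a canonical head placed with its face plane at
`y = -face_to_iso`, source anterior (gantry 0). Room-vertical is patient
`-y` at couch 0 (supine), the gantry axis is patient `+z` at couch 0, and the
gantry angle increases toward patient-left (gantry 90 puts the source on the
patient's left), the Varian IEC sense; a `chirality` flag flips it for other
scales. The couch rotation is applied to the *machine* with a negated angle —
the patient and couch meshes never move, which keeps every clearance in one
fixed frame. Every sign in this pinning is covered by the mirror-symmetry
test: for a laterally symmetric scene,
`clearance(g, c) = clearance(360 - g, (360 - c) mod 360)`, and the test suite
verifies this to below `1e-6` cm over the full validation sweep.

## The clearance objective

Clearance between two structures is the exact minimum over all
**vertex pairs** of the Euclidean distance. This is deliberately not a
point-to-surface distance: the clinical tool family this package models works
on contour vertex clouds, and the vertex-pair objective makes the accelerated
query *provably exact* (both the brute-force oracle and the tree traversal
minimize over the identical finite set, with the identical arithmetic, so
tests can assert bitwise equality). The price is that a reported clearance can
exceed the true surface clearance by up to the local edge length of the
meshes. That bias is one of the reasons the safety margin exists and is why
phantom fixtures expose mesh resolution as a parameter. An exact
point-to-triangle refinement was considered and excluded: it would change the
objective the validation statistics were built on.

## The OBB tree and why the traversal is exact

Each structure's vertices are fitted with an oriented bounding box from the
eigenvectors of the point covariance (eigenvalues descending; each axis's
sign fixed by making its largest-magnitude component positive, so fits are
deterministic). Top-down construction splits a node's vertex set by the plane
through the box center normal to the longest axis; if that plane fails to
separate (coincident or one-sided clouds), a median split along the same axis
is forced, which guarantees termination. Leaves hold at most `leaf_capacity`
vertices (default 8 — small enough to prune tightly, large enough that leaf
blocks vectorize well).

Queries are best-first branch-and-bound over node pairs. The bound is the
largest positive separation gap over the 15 separating-axis candidates of the
two boxes, which is a *valid lower bound* on the box-box distance along any
unit axis (and 0 exactly when the SAT test reports overlap). A subtree pair
is discarded only when this bound is at least the best vertex-pair distance
found so far, so pruning can never remove the optimum: the returned distance
equals the exhaustive scan exactly. A GJK-style exact box-box distance would
give tighter bounds and fewer node visits, but a valid bound is all
exactness requires, and the SAT gap reuses the overlap test's arithmetic;
measured pruning on well-separated 1000-vertex clouds already tests under
0.1% of the 10^6 vertex pairs. Traversal order is deterministic
(nearer-bound child first, ties by child index), and each query returns
`Nv`/`Np` cost counters so efficiency claims are measurable rather than
asserted.

Boolean collision queries accept an `early_exit` flag that stops as soon as
any pair is found inside the margin. It is **off by default** so that reported
minima are true minima (needed for minimum-clearance displays); when on, the
reported distance is flagged as an upper bound.

## Machine model

The gantry head is parametric: a casing extruded from a
circumference-vs-height profile (linearly interpolated between measured
heights; only the 14 cm of casing nearest the face — the part that can
plausibly collide — is modeled), a triangulated face, and cylindrical bosses
for the major face projections (locking pins, tray insert). Defaults produce
1541 vertices, within the +/-20% band around the 1639-vertex reference CAD
model the parametrization emulates. `face_to_iso` (default 40 cm) is a
machine-specific placeholder that users must calibrate to their installation;
no test treats it as ground truth. Because everything behind the modeled
casing is absent, clearances to structures far behind the face plane are not
meaningful — the same limitation the modeled-casing design always has.

## Registration

Add-on structures (shoulder/chest additions for chin-to-crown scans, detailed
couch boards) are placed by translation only, from extremal coordinates: the
add-on's posterior datum to the body's posterior extreme, its lateral midline
to the body's lateral midpoint, and its superior face to the body's inferior
extreme (body additions) or to the body's superior extreme minus a head
offset (couch structures). The add-on-side datums are this package's
construction — the clinical description of this alignment fixes only the
body-side extremes — and are declared explicitly on each mesh (JSON sidecar in the
add-on library) rather than guessed from geometry. Rotational registration is
excluded on purpose: couch-mounted hardware shares the patient frame axes,
and a pure translation is reproducible and manually adjustable
(`apply_manual_offset`). A couch structure registered this way typically ends
up partly inside the body contour (the board head is contained in the body
contour clinically); the extents-overlap advisory is therefore a warning, not
an error.

## Trajectory testing

Arcs are sampled every `step_deg` (default 5 degrees) from the start control
point along the travel direction, wrapping through 0/360, with both control
points always included even off the lattice (they are physical limits of
travel). Collisions *between* samples are not detected — a discrete sampler
cannot — which is a second reason the margin is mandatory. Body and couch are
tested as separate targets with separate witnesses, and the per-beam overall
minimum breaks ties by earliest position along travel (body before couch at
the same angle).

Risk labels: `CollisionRisk` iff distance `< margin` (strict: a pose at
exactly the margin is safe), `NearCollisionRisk` on `[margin, margin +
near_band)` with the default 10 cm band half-open at the top. One collimator
angle is used per beam, not per control point, matching how plans specify it.
The maximum-range search scans the full gantry lattice at one couch angle and
returns maximal circular runs of safe angles, which is how conservative
clinical arcs can be widened.

## Validation module and the synthetic measurement model

Confusion counts follow the standard 2x2 table; NPV is `TN/(TN+FN)` and is
exactly 1 whenever `FN = 0`; percentages print rounded half-up to one
decimal, the convention of the published table this module reproduces (the
published count quadruples ship with the package as
`roc_reference_counts()`).

Physical caliper measurements are replaced by a synthetic generator:
`measured = max(0, true + e)` with `e ~ N(bias, sd^2)` optionally truncated to
`|e| <= max_abs_error`. The published error distribution (mean -0.2 cm,
SD 0.7 cm, worst cases -2.9/+2.4 cm) motivates the defaults, and the
truncation bound 2.9 cm expresses the observed worst case. Censoring at zero
(rather than resampling) is intentional: a caliper cannot read a negative
clearance, and contact reads exactly zero, which is what defines "actual
collision" in margin sweeps — `measured <= threshold` with threshold 0. The
inclusive comparison is required by that censoring: contact produces exactly
0, and a strict comparison would make physical collisions unobservable. Under
the truncated model, any pose in physical contact has a calculated distance
below 2.9 cm, so a 3 cm margin deterministically yields zero false negatives;
the acceptance suite verifies this across 100 seeds, alongside the structural
monotonicity of FP (non-decreasing) and FN (non-increasing) in the margin.

What the synthetic generator does **not** emulate: contour segmentation
error, couch sag and skin deformation, inter-observer caliper variation, and
any spatial correlation of errors across neighboring poses. Green tests
therefore demonstrate algorithmic correctness and the margin logic, not
clinical measurement fidelity; site commissioning against physical
measurements remains necessary.

## Fixtures and problem sizes

The cuboid calibration phantom (30 x 20 x 20 cm at 2 cm resolution, 802
vertices, exactly symmetric about the midsagittal plane) and the default
gantry head (1541 vertices) are the workhorse pair: large enough that pruning
matters, small enough that the brute-force oracle stays cheap. The test suite
uses 50 random mesh pairs up to 500 vertices for oracle equivalence, 500
random box pairs against an alternating-projection convex-distance oracle for
the SAT test, the full 13-couch x 72-gantry lattice for the symmetry audit,
and 100 seeds x 702 poses for margin sweeps; the whole suite and the
acceptance script each run in a few minutes on one CPU. The
`collision_demo` scene manufactures an exactly intersecting pose by placing a
grid vertex of the block at the gantry face center's gantry-0 position, and
verifies it by brute force at construction time.

## Numerical choices

* STL vertex welding is exact (bitwise coordinate equality via hex-float
  keys); a tolerance weld could merge distinct vertices and silently change
  the distance objective.
* Brute force and leaf blocks share one distance kernel
  (`|a|^2 + |b|^2 - 2ab`, clamped at 0), so the two code paths agree exactly,
  not approximately; equidistant vertex pairs break ties lexicographically on
  `(index_a, index_b)`.
* Degenerate SAT cross-product axes (parallel edges, squared norm below
  1e-24) are skipped; boxes touching exactly count as overlapping.
* OBB containment is audited with a 1e-7 cm inflation to absorb roundoff.
* Angles outside [0, 360) are normalized with a warning rather than rejected;
  an exactly zero-length arc without the static-beam flag is an error.

## Known limitations

Vertex-pair clearance overestimates surface clearance (bounded by edge
length); 5-degree sampling misses between-sample grazes; the head model stops
14 cm behind the face; imaging arms, electron applicators, and couch
translations beyond the isocenter shift are out of scope; phantoms are
schematic, not anthropometric. All are absorbed operationally by the clinical
5 cm margin, whose adequacy the validation module is designed to test — not
assume.
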
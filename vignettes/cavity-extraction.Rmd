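---
title: "Landmark-guided cavity extraction and alpha-shape volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-guided cavity extraction and alpha-shape volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavex)
```

## The problem

Skeletal cavities — the nasal cavity, the paranasal sinuses, the orbits, the
upper oral volume — are bounded partly by bone and partly by openings, so
they have no watertight boundary of their own. Measuring their volumes from
CT-derived surface meshes traditionally means slice-by-slice manual
segmentation, which is slow and operator-dependent. `cavex` automates the
measurement: a configuration of named anatomical landmarks anchors cutting
planes and viewpoints, the cavity-of-interest (COI) surface is pulled out of
the cranial mesh by geometric rules alone, and its volume is read off a 3D
alpha-shape built around the extracted surface.

The input is a triangle mesh in millimetres (PLY, STL or OBJ), downsampled
once to at most 500,000 triangles, plus a landmark CSV. The shipped
`icex18` schema names the 18 cranial points (bregma through prosthion) used
by the full protocol; free configurations are accepted for single cavities
or other skeletal elements.

## The four extraction modes

Each cavity is described declaratively by a `mode_spec()`:

* **Mode 1** (nasal cavity: 5 planes; each maxillary sinus: 6 planes).
  Cutting planes through landmark triplets isolate the bone region housing
  an enclosed cavity; `extract_enclosed_cavity()` then seeds an interior
  point and collects the surface visible from it.
* **Mode 2** (orbits; edentulous palate). No cutting: the barycentre of
  three landmarks is a point of view (POV), and the COI is the surface
  visible from it.
* **Mode 3** (palate with teeth). One alveolar plane removes the tooth row,
  then Mode 2.
* **Mode 4** (frontal sinuses). Two planes isolate a bone slab;
  multi-viewpoint "laser-scanner" visibility marks its external surface and
  the invisible complement is split into connected pneumatised cells,
  measured all together (`multiple = TRUE`) or only the biggest.

Half-space cutting splits straddling triangles exactly at the plane rather
than dropping them whole; whole-triangle dropping biases cavity openings by
up to one triangle and makes volumes resolution-dependent. Vertices within
1e-9 mm of a plane belong to both sides. The keep side is the sign of
`dot(x - origin, normal)` with the triplet order defining the normal; this
convention is covered by tests, since conventions differ between tools.

### Interior seeding for enclosed cavities

Mode 1 must find a point inside a void it has never seen. Axis-aligned rays
are cast through the cut region; midpoints of the intervals between
consecutive surface crossings are candidate seeds. Two filters follow.
First, enclosedness: every one of 14 probe rays from the candidate must hit
the mesh, which discards points that can see open space through the cut
openings. Second, orientation: a candidate must mostly face triangle
*fronts*. Under the outward-from-bone orientation convention that
iso-surface reconstructions produce, a cavity wall's normals point into its
void, while the inside of a plain closed shell sees only triangle backs —
this is what distinguishes an enclosed cavity from the interior of solid
bone, which a surface mesh otherwise cannot express. The surviving
candidate with the greatest clearance to the surface wins, and the COI is
the union of the surfaces visible from it and from six surrounding POVs
(offset by a quarter of the clearance, scaled by `param1`).

### Visibility

A vertex is visible from a POV when the open segment between them (shortened
by 1e-4 mm at both ends, so near-coincident geometry does not self-occlude)
intersects no triangle, with the triangles incident to the target vertex
excluded; a ray through an edge counts as blocked. Faces are kept when all
three corners are visible — the conservative rule that avoids bleeding
through ostia; `any` and `majority` are available for heavily decimated
meshes. The accelerated implementation walks a bounding-volume hierarchy
and is required by a test to agree *exactly* with the all-pairs
segment-triangle oracle, so acceleration can never change semantics.
Scanner emulation places POVs at the vertices of a subdivided icosahedron
(uniform on the sphere; 642 by default) at 1.5 bounding-sphere radii, and a
vertex is external when any POV sees it.

## Volume by alpha-shape

The COI is an open surface; the alpha-shape closes it. The vertex cloud is
Delaunay-tetrahedralised and every tetrahedron with circumradius at most
`alpha` is kept: at `alpha = Inf` the complex is the convex hull, and
smaller values fit the envelope more tightly. Near-degenerate slivers are
assigned infinite circumradius so they drop out at any finite alpha.

Volume is reported twice. The *voxel* estimate lays a grid of spacing
`alpha/20` (by default) over the complex and counts voxels whose centre
lies in the complex and whose cube contains no COI vertex — the empty-voxel
reading, with vertices assigned to cubes by a half-open `[low, high)`
convention so space is partitioned deterministically. The *tetra* estimate
is the exact sum of kept tetrahedron volumes and serves as the oracle: the
two converge as the spacing shrinks, and a test requires the gap to halve
when the spacing halves.

Choosing `alpha` matters. It must exceed the largest empty-sphere radius of
the cavity so that interior tetrahedra survive; for a spherical cavity of
radius `r` *every* interior tetrahedron has circumradius close to `r` (its
empty circumsphere is essentially the cavity sphere itself), so any
`alpha < r` yields an empty complex and the error message reports the
smallest workable alpha. For convex cavities a generous alpha is safe — the
complex cannot exceed the hull. The data-driven default (twice the 95th
percentile of COI edge lengths) suits tight, well-sampled walls and should
be overridden per cavity; `param2` scales it for unusually large cavities.
Volumes are divided by 1000 and reported in cm^3.

### Numerical choices

The Delaunay construction is incremental with a symbolic vertex at infinity
(ghost tetrahedra), so the finite tetrahedra tile the convex hull exactly —
a property a test verifies against an independently implemented quickhull
at 1e-9 relative tolerance. Predicates are plain doubles; every completed
triangulation is validated (ghost faces must form a closed convex surface
whose enclosed volume the tetrahedra fill exactly), and on any failure the
construction restarts with a fresh insertion order and a deterministic
jitter that grows geometrically from 1e-8 of the bounding box. Structured
clouds — grids, cospherical points — take the jitter path; generic clouds
are triangulated as given, which is why the hull-limit property holds to
machine precision on random data.

## The phantom generator

`make_phantom()` builds watertight surrogate "crania" whose cavities have
closed-form volumes, so the whole protocol is testable without imaging
data: a hollow sphere (`4/3*pi*r^3`), a block with an enclosed box cavity
(5-plane Mode-1 recipe), an open orbit socket (cylindrical collar +
hemisphere, Mode 2), a palate dome (box + half-cylinder vault with a tooth
row, Mode 3), a slab with two pneumatised cells (Mode 4), and a full-suite
cranium carrying all five cavities with the complete 18-landmark scheme:

```{r suite, eval = FALSE}
b <- make_phantom("full-suite")
out <- run_icex(b$mesh, b$landmarks, b$specs, outdir = "suite_out")
evaluate_extraction(b, out$results)
```

Design choices worth knowing:

* Phantom faces are assembled from grid patches that sample shared per-axis
  break vectors, so adjacent patches meet vertex-for-vertex and a single
  weld yields a 2-manifold; orientation is fixed afterwards by a
  consistency pass that points the outer shell outward and every cavity
  wall into its void.
* Landmarks sit at exact analytic positions (several double as generators
  of two or three cutting planes at once); a separate `jitter_landmarks()`
  utility adds Gaussian noise for robustness checks, keeping correctness
  tests and noise tests apart. Every plane's three generators form a wide
  triangle: a plane through clustered or nearly collinear points
  lever-amplifies millimetre placement noise into multi-millimetre tilt at
  the far side of the cranium, which is the dominant failure mode of
  landmark-driven cutting — a consideration that applies to real landmark
  schemes just as much as to phantoms.
* Cavity walls keep at least 3 mm of clearance from every cutting plane —
  several standard deviations of the 0.5 mm observer-scale noise used in
  the robustness test, so a jittered plane cannot graze a wall. (A margin
  of twice the default alpha, attractive in principle, is geometrically
  impossible inside a 120 mm cranium holding five separated cavities.)
* The alveolar plane of the palate recipes passes through the tooth *roots*
  (2 mm below the palate opening) rather than the opening plane itself:
  anatomically the alveolar limit, and it keeps the measured oral volume
  insensitive to plane noise, since the cut then never clips the dome.
* The frontal-sinus slab works because the cranial vault is a sandwich:
  a thin endocranial void spans almost the whole vault footprint, so after
  the z-cut the only ways into the sandwich are millimetre slots whose
  grazing rays cannot reach the cells. One of the two Mode-4 planes is
  tangent (outside the cranium) — cutting a second wide window anywhere
  would expose the cells to the scanner, the geometric analogue of cutting
  a real frontal bone somewhere other than its thin diploic edge.
* The two cell volumes differ (4.0 and 3.2 cm^3 in the suite; 1.5 and
  0.8 cm^3 in the standalone slab) so the `multiple = FALSE` path has a
  well-defined "biggest cell".

What passing phantoms does *not* show: real crania have curved, rough,
sometimes damaged surfaces, partial landmark visibility, and cavities whose
openings are not flat; the phantoms emulate topology and metric truth, not
cranial shape variation, CT noise, or sediment infill. Results on real
material still require the usual visual QC (the exported COI + alpha-shape
renders).

## Problem sizes and runtime

The default test and acceptance runs use the suite phantom at about 24,000
triangles, scanner visibility with 642 viewpoints, alpha-shapes over
clouds of 10^3-10^4 points and voxel grids of order 10^5-10^6 cells; the
five-cavity suite completes in a few seconds on one core. Convergence
checks (voxel-gap halving) use finer phantoms (`mesh_resolution = 2-3`) so
that the voxel spacing stays above the mesh edge length, the regime in
which the one-voxel-shell error model — gap proportional to spacing —
applies.

## Known limitations

* The enclosed-cavity orientation test assumes the outward-from-bone
  convention; meshes with deliberately inconsistent orientation fall back
  to treating any enclosed void as a cavity.
* `alpha` is a single scalar per cavity; strongly anisotropic cavities may
  need the `multiple` pathway or manual editing of the exported COI
  (`icv()` accepts re-loaded meshes).
* Binary STL stores 32-bit floats; round-trips through it lose precision
  beyond ~1e-5 relative. PLY or OBJ round-trip to better than 1e-6 mm.
* Plane recipes for real crania (which triplets bound which cavity) are
  editable configuration, not anatomy fixed by the package; the shipped
  phantom recipes document the convention.
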
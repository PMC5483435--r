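---
title: "Segment-based processing of compressed tractograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-based processing of compressed tractograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segtract)
```

## The problem

Tractography reconstructs white-matter pathways as *streamlines*: ordered 3D
polylines in world millimeters, typically sampled at a small uniform step
(0.5 mm here). Whole-brain tractograms run to millions of streamlines, so a
standard space-saving move is to discard (near-)collinear points under an
error bound. That compression breaks every downstream tool that reasons
about streamline *points* rather than *segments*: a region of interest (ROI)
placed on a straight stretch of a compressed tract may contain no surviving
point at all, and a voxel crossed by a long chord may never receive a point.
`segtract` implements the three pieces needed to make compression safe:

1. **Linearization** — error-bounded point removal with two parameters, the
   maximum error threshold (MET) and the maximum linearization distance
   (MLD).
2. **Progressive selection** — ROI-based streamline selection that is exact
   on compressed data, combining a fast octree point phase with
   segment–mesh intersection over an *extended neighborhood*.
3. **Segment-based tractometry** — voxel mapping by grid traversal rather
   than point flooring, giving bundle statistics that barely move under
   compression.

All coordinates are world RAS millimeters internally; TRK's voxel-mm dialect
is converted at the I/O boundary, since every algorithm's thresholds are
stated in mm.

## Linearization

`linearize_streamline()` runs a greedy forward scan with *backward
verification*. From the last kept point, a candidate end point advances one
input point at a time; at each advance all intermediate points are re-tested
against the chord from the kept point to the candidate. Three cases:

* **A** — all intermediate points lie within `met` of the chord and the
  candidate is within `mld` (Euclidean) of the kept point: advance.
* **B** — an intermediate point exceeds `met`: keep the *previous*
  candidate (the last one that passed) and restart from it.
* **C** — the candidate exceeds `mld` (strictly): same restart.

Keeping the last passing candidate (rather than the violating point) makes
the error bound hold by construction: every discarded point is within `met`
of its enclosing kept chord. Distances are measured to the infinite line
through the chord's endpoints — the standard collinearity test; intermediate
points project inside the chord in practice. `met = 0` removes only
exactly collinear points, with a 1e-12 mm tolerance absorbing float noise.
Inputs whose own steps exceed `mld` violate the precondition; both endpoints
of such a step are kept and the output bound degrades to the input's longest
step. Defaults are `met = 0.2` mm and `mld = 5` mm, the configuration used
for the reference timing and probabilistic-tracking experiments.

```{r linearize}
s <- cbind(seq(0, 30, by = 0.5), 0, 0)   # 61 points, exactly straight
linearize_streamline(s, linearization_params(met = 0.1, mld = 10))
```

The distance cap fires at each 10.5 mm candidate, so only x = 0, 10, 20, 30
survive. On curved geometry the error threshold binds first, which is why
high-curvature bundles (corpus callosum) compress less than straight ones
(corticospinal tract).

## Progressive selection

ROIs are closed triangle meshes — boxes, subdivided-icosphere ellipsoids, or
external OBJ/PLY surfaces — validated watertight at construction. Phase 1
queries an octree of all streamline points with the ROI's bounding box and
tests the candidates for mesh inclusion (ray parity, boundary inclusive
within 1e-9 mm, so the point test and the segment test agree at faces).
Phase 2 expands the bounding box by the extended-neighborhood size `L` on
every side, collects not-yet-selected streamlines' points there, and tests
their (up to two) incident segments against the mesh with a
Möller–Trumbore intersection test.

With `L` = the tractogram's maximum segment length, any segment touching the
mesh must have an endpoint in the expanded box, so the result provably
equals the exhaustive scan (`brute_force_select()` asserts this on every
generated phantom). With `L` = the mean segment length the phase is faster
but may miss streamlines; `missed_fraction()` quantifies the loss of any
point-only or heuristic variant against the complete result. The octree
uses leaf capacity 64 and maximum depth 10, and points exactly on a split
plane go to the lower child, making the structure deterministic.

## Segment-based tractometry

`traverse_segment()` walks a segment through the voxel grid
(Amanatides–Woo): voxels are half-open cubes `[i,i+1)` in grid coordinates,
so flooring a grid coordinate is the point→voxel map and no boundary is
counted twice. When a segment hits a cube edge or corner exactly, axes step
in fixed x→y→z order, deterministically including the intermediate voxel.
Segments are clipped to the grid; out-of-grid points contribute nothing.

`bundle_weight_map()` accumulates per-voxel occupancy. The default
weighting, `per_streamline`, adds 1 per streamline per traversed voxel; in
segment mode this is the only weighting invariant under collinear
resampling — the whole point of segment-based mapping, since compression is
exactly a resampling of the polyline. `per_sample` (1 per point, or per
segment-voxel crossing) reproduces the resolution-dependent baseline whose
weight loss under compression the difference map
(`weight_difference_map()`) visualizes. `bundle_summary()` reports the
binarized and occupancy-weighted means of a scalar map over the traversed
voxels, plus the voxel count and volume; `robustness_statistic()` is the
relative change `R = |M_c − M_0| / |M_0|` of a bundle mean under
compression. R is computed from the weighted mean by default; either mean
can be supplied.

## Synthetic phantoms

No acquisition accompanies the reference experiments, so every test runs on
seeded generators. `phantom_spec()` builds bundles of exactly uniform step
(0.5 mm default, the reference tracking step) on a 50³ grid of 2 mm
isotropic voxels (the acquisition resolution): straight lines and circular
arcs emulate smooth deterministic tracking (the arc's radius controls the
curvature contrast between CC-like and CST-like anatomy); `random_walk`
emulates probabilistic tracking by rotating the direction each step by a
folded-normal angle (stated σ, uniform azimuth in the orthogonal plane) —
one knob for "sharp local direction changes". Streamlines are the
centerline offset by a uniform disk sample of the cross-section radius
(2 mm default). Scalar maps are closed forms at voxel centers (constant,
axis gradient, radial distance).

`canonical_scenario()` packages the two canonical geometries: `cc_like`, a
180° arc of 20 mm radius with a 5×5×5 mm cubic ROI at the apex, and
`cst_like`, a nearly straight bundle with the same cube midway. `cst_like`
deliberately uses a 2°/step walk rather than an exact line: linearizing an
exact line keeps points on a regular once-per-MLD lattice, and whether a
grid-aligned ROI contains a kept point is then a parity accident — a
degeneracy real tracts do not have. What the phantoms do *not* emulate:
fiber crossings, partial-volume effects, realistic FA contrast, or
tracking-error anatomy; passing tests show algorithmic correctness on
controlled geometry, not clinical validity.

## Numerical choices

* Grid convention: voxel `(i,j,k)` occupies `[i,i+1)³` after a +0.5 shift
  from the center-based affine; lower faces inclusive.
* Mesh tolerances: 1e-9 mm inclusive at surfaces; 1e-12 barycentric slack;
  parity rays use a fixed irrational-direction vector so grid-aligned
  points essentially never graze an edge.
* Traversal oracle testing uses segments in generic position: consecutive
  grid-plane crossing parameters at least 2.5e-4 apart, so a 10⁴-sample
  supersampling oracle lands at least one sample in every traversed voxel.
* Consecutive duplicate points are dropped at load (zero-length segments
  break distance and traversal arithmetic); sub-2-point streamlines are
  rejected.
* Test problem sizes: the linearization invariant suite uses 200
  streamlines × 4 MET × 3 MLD values; selection completeness uses 50
  random phantom/ROI pairs (compressed and uncompressed); the traversal
  oracle uses 10⁴ random segments; the tractometry bias ordering uses 20
  seeded curved bundles of 50 streamlines with majority voting.

## A pipeline

```{r pipeline}
sc <- canonical_scenario("cst_like", seed = 42)
lc <- linearize_tractogram(sc$tractogram, linearization_params(0.3, 10))
lc$report

idx <- build_point_index(lc$tractogram)
sel <- select_progressive(lc$tractogram, idx, sc$roi)
sel

m0 <- bundle_summary(bundle_weight_map(sc$tractogram), sc$metric)
mc <- bundle_summary(bundle_weight_map(lc$tractogram, ref = sc$ref), sc$metric)
robustness_statistic(m0$mean_weighted, mc$mean_weighted)
```

The same pipeline is scriptable from a shell via the `segtract` launcher in
`exec/` (`generate`, `compress`, `select`, `tractometry`, `robustness`),
with YAML config files, atomic output writes, and one global `--seed`
driving all randomness.

## Limitations

* The heuristic neighborhood is intentionally incomplete; use `complete`
  (the default) whenever correctness matters.
* Point-in-mesh parity assumes a watertight mesh; construction validates
  this, but a self-intersecting external mesh can still fool the parity
  test.
* Compression is point removal only; no byte-level encoding, no
  decompression/re-interpolation, and no dedicated on-disk tag for
  compressed data is emitted.
* Published absolute selection counts and bundle means depend on a
  non-deposited single-subject acquisition and are out of reach by design;
  the package reproduces the arithmetic identities among printed values and
  the qualitative orderings on synthetic data.
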
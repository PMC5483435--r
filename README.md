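# segtract

Segment-based processing of compressed diffusion-MRI tractograms.

Tractography compression removes (near-)collinear streamline points under an
error bound, leaving polylines with long, irregular segments. Most
interaction and statistics code is *point-based* — it only looks at the
surviving vertices — and silently breaks on such data: ROI selection misses
streamlines whose points were discarded, and bundle statistics drift because
voxels crossed by long chords never receive a point. `segtract` is for
researchers and tool builders who need compression-safe tractogram
processing in R:

* **Linearization** (`linearize_streamline()`, `linearize_tractogram()`):
  greedy forward scan with backward verification under two parameters — the
  maximum error threshold MET (mm), bounding the perpendicular distance of
  every discarded point to its replacing chord, and the maximum
  linearization distance MLD (mm), bounding the Euclidean distance between
  consecutive kept points. Defaults: MET 0.2 mm, MLD 5 mm.
* **Progressive ROI selection** (`select_progressive()`): an octree
  point-inclusion phase, completed by segment–mesh intersection restricted
  to the ROI's bounding box expanded by the *extended neighborhood* size L.
  With L = the maximum segment length the result provably equals an
  exhaustive scan; L = the mean segment length is a faster, possibly
  incomplete heuristic. `missed_fraction()` reports
  `100 · (complete − point) / complete`, the percentage a point-only
  selection misses.
* **Segment-based tractometry** (`traverse_segment()`,
  `bundle_weight_map()`, `bundle_summary()`): Amanatides–Woo grid traversal
  maps every voxel a segment crosses, so occupancy maps and bundle means
  are (nearly) invariant under compression. The robustness statistic
  `R = |M_c − M_0| / |M_0|` (`robustness_statistic()`) quantifies how far a
  bundle-mean metric M moves when the bundle is compressed at threshold c.

TCK (MRtrix) and TRK (TrackVis) files are read and written natively
(`read_tractogram()`, `write_tractogram()`), with TRK's voxel-mm dialect
converted to world RAS mm at the boundary; scalar maps use NIfTI via
RNifti. Seeded synthetic generators (`phantom_spec()`, `generate_bundle()`,
`analytic_metric()`, `canonical_scenario()`) provide reproducible bundles,
ROIs and metric maps for every test.

## Worked example

A straight-ish 50-streamline bundle with a 5×5×5 mm cubic ROI midway and an
axis-gradient scalar map:

```r
library(segtract)

sc <- canonical_scenario("cst_like", seed = 42)
lc <- linearize_tractogram(sc$tractogram, linearization_params(met = 0.3, mld = 10))
lc$report
#> Compression: 6050 -> 388 points (93.6% discarded)

idx <- build_point_index(lc$tractogram)
select_progressive(lc$tractogram, idx, sc$roi)
#> Selection: 19 streamline(s) [16 point phase + 3 segment phase], L = 10 mm

m0 <- bundle_summary(bundle_weight_map(sc$tractogram), sc$metric)
mc <- bundle_summary(bundle_weight_map(lc$tractogram, ref = sc$ref), sc$metric)
robustness_statistic(m0$mean_weighted, mc$mean_weighted)
#> R = |0.51142 - 0.51199| / |0.51199| = 0.00110 (0.11%)
```

Compression discards 93.6% of the points. A point-only selection would have
returned 16 streamlines; the segment phase recovers 3 more that still cross
the ROI (`missed_fraction(16, 19)` = 15.79%). The segment-based weighted
mean moves by 0.11% under this compression; rerunning the last block with
`mode = "point"` gives 1.92% — the point-based bias the segment method
removes.

The same pipeline runs from a shell through the `segtract` script installed
from `exec/` (subcommands `generate`, `compress`, `select`, `tractometry`,
`robustness`; `--config` accepts a YAML file, all randomness flows from
`--seed`).

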
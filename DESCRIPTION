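Package: segtract
Title: Segment-Based Processing of Compressed Tractograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diffusion MRI tractograms whose streamlines have been
    compressed by collinear-point removal. Implements error-bounded streamline
    linearization with a maximum error threshold and a maximum linearization
    distance, progressive region-of-interest selection that combines an octree
    point phase with segment-mesh intersection over an extended neighborhood,
    and segment-based (voxel traversal) tractometry that removes the voxel
    mapping bias of point-based statistics. Reads and writes TCK (MRtrix) and
    TRK (TrackVis) streamline files and NIfTI scalar maps, and ships seeded
    synthetic bundle and metric generators for fully reproducible testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    tools,
    yaml,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
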
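test_that("octree range queries equal brute-force point-in-box scans", {
  ref <- identity_ref(c(20L, 20L, 20L))
  t1 <- tractogram(list(rbind(c(5, 5, 5), c(5.2, 5, 5))), ref)
  idx1 <- build_point_index(t1)
  q <- query_point_index(idx1, c(4, 4, 4), c(6, 6, 6))
  expect_equal(q$sid, c(1L, 1L))
  expect_equal(q$pidx, c(1L, 2L))
  expect_equal(nrow(query_point_index(idx1, c(10, 10, 10), c(12, 12, 12))$points), 0L)

  set.seed(21)
  sl <- replicate(100, matrix(runif(300, 0, 20), ncol = 3), simplify = FALSE)
  t <- tractogram(sl, ref)
  idx <- build_point_index(t, leaf_capacity = 32L)
  all_pts <- do.call(rbind, t$streamlines)
  for (i in 1:100) {
    lo <- runif(3, 0, 18)
    hi <- lo + runif(3, 0.5, 6)
    got <- query_point_index(idx, lo, hi)
    want <- which(all_pts[, 1] >= lo[1] & all_pts[, 1] <= hi[1] &
                  all_pts[, 2] >= lo[2] & all_pts[, 2] <= hi[2] &
                  all_pts[, 3] >= lo[3] & all_pts[, 3] <= hi[3])
    expect_setequal(
      paste(got$sid, got$pidx),
      paste(idx$sid[want], idx$pidx[want]))
  }
})

test_that("box and ellipsoid ROI meshes are watertight with the right extent", {
  b <- box_roi(c(0, 0, 0), c(0.5, 0.5, 0.5))
  expect_equal(nrow(b$triangles), 12L)
  expect_equal(b$aabb, rbind(min = c(-0.5, -0.5, -0.5), max = c(0.5, 0.5, 0.5)))

  cube5 <- box_roi(c(10, 10, 10), c(2.5, 2.5, 2.5))   # a 5 x 5 x 5 mm ROI
  expect_equal(cube5$aabb["max", ] - cube5$aabb["min", ], c(5, 5, 5))

  e <- ellipsoid_roi(c(1, 2, 3), c(1, 1, 1), subdivisions = 2L)
  r <- sqrt(rowSums(sweep(e$vertices, 2, c(1, 2, 3))^2))
  expect_true(all(abs(r - 1) < 1e-6))

  # a rotated box is still watertight and sized by its vertices
  th <- 0.4
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rb <- box_roi(c(0, 0, 0), c(1, 2, 3), rotation = rot)
  expect_s3_class(rb, "roi_mesh")
  expect_error(box_roi(c(0, 0, 0), c(1, 1, 1), rotation = matrix(1, 3, 3)),
               "orthonormal")
  expect_error(box_roi(c(0, 0, 0), c(0, 1, 1)), "positive")

  # tampering with a face breaks watertightness
  expect_error(roi_mesh(b$vertices, b$triangles[-1, ]), "watertight")
})

test_that("point-in-mesh matches the analytic box inequality", {
  expect_true(point_in_mesh(c(0, 0, 0), box_roi(c(0, 0, 0), c(0.5, 0.5, 0.5))))
  expect_false(point_in_mesh(c(2, 0, 0), box_roi(c(0, 0, 0), c(0.5, 0.5, 0.5))))
  expect_true(point_in_mesh(c(0.5, 0, 0), box_roi(c(0, 0, 0), c(0.5, 0.5, 0.5))))

  set.seed(33)
  center <- runif(3, 4, 6)
  half <- runif(3, 0.5, 2)
  roi <- box_roi(center, half)
  P <- matrix(runif(3000, 2, 8), ncol = 3)
  inside <- points_in_mesh(P, roi)
  analytic <- abs(P[, 1] - center[1]) <= half[1] &
              abs(P[, 2] - center[2]) <= half[2] &
              abs(P[, 3] - center[3]) <= half[3]
  expect_equal(inside, analytic)
})

test_that("segment-mesh intersection matches slab clipping on boxes", {
  roi <- box_roi(c(0, 0, 0), c(0.5, 0.5, 0.5))
  expect_true(segment_intersects_mesh(c(-1, 0, 0), c(2, 0, 0), roi))
  expect_true(segment_intersects_mesh(c(-0.1, 0, 0), c(0.1, 0.1, 0), roi))  # inside
  expect_false(segment_intersects_mesh(c(2, 2, 2), c(3, 3, 3), roi))
  expect_error(segment_intersects_mesh(c(1, 1, 1), c(1, 1, 1), roi), "degenerate")

  set.seed(44)
  center <- runif(3, 4, 6)
  half <- runif(3, 0.5, 2)
  roi2 <- box_roi(center, half)
  lo <- center - half
  hi <- center + half
  P0 <- matrix(runif(1500, 2, 8), ncol = 3)
  P1 <- P0 + matrix(runif(1500, -3, 3), ncol = 3)
  got <- segments_hit <- vapply(seq_len(nrow(P0)), function(i)
    segment_intersects_mesh(P0[i, ], P1[i, ], roi2), logical(1))
  want <- vapply(seq_len(nrow(P0)), function(i)
    slab_clip_hits_box(P0[i, ], P1[i, ], lo, hi), logical(1))
  expect_equal(got, want)
})

test_that("progressive selection resolves the three neighborhood cases", {
  ref <- identity_ref(c(20L, 20L, 20L))
  cube <- box_roi(c(10.5, 10.5, 10.5), c(0.5, 0.5, 0.5))   # box [10,11]^3
  # A: point inside; B: long segment crossing, no point inside; C: far away
  t <- tractogram(list(
    rbind(c(10.5, 10.5, 10.5), c(12, 12, 12)),
    rbind(c(9, 10.5, 10.5), c(12, 10.5, 10.5)),
    rbind(c(3, 3, 3), c(4, 4, 4))
  ), ref)
  idx <- build_point_index(t)
  res <- select_progressive(t, idx, cube, neighborhood = 3)
  expect_equal(res$phase1_ids, 1L)
  expect_equal(res$phase2_ids, 2L)
  expect_equal(res$selected, c(1L, 2L))
  expect_equal(res$neighborhood_mm, 3)
  # disjointness and union are structural
  expect_length(intersect(res$phase1_ids, res$phase2_ids), 0L)
  expect_setequal(union(res$phase1_ids, res$phase2_ids), res$selected)
  expect_error(select_progressive(t, idx, cube, neighborhood = -1), "> 0")
})

test_that("complete selection equals brute force; heuristic never exceeds it", {
  for (seed in 1:12) {
    pair <- random_phantom_roi(seed)
    t <- pair$tractogram
    idx <- build_point_index(t)
    bf <- brute_force_select(t, pair$roi)
    complete <- select_progressive(t, idx, pair$roi, "complete")
    heuristic <- select_progressive(t, idx, pair$roi, "heuristic")
    expect_identical(complete$selected, bf)
    expect_true(all(complete$phase1_ids %in% complete$selected))
    expect_true(all(heuristic$selected %in% complete$selected))
  }
})

test_that("selection stays complete after compression", {
  for (seed in 13:18) {
    pair <- random_phantom_roi(seed)
    tc <- linearize_tractogram(pair$tractogram,
                               linearization_params(0.3, 10))$tractogram
    idx <- build_point_index(tc)
    expect_identical(select_progressive(tc, idx, pair$roi, "complete")$selected,
                     brute_force_select(tc, pair$roi))
  }
})

test_that("selected sets grow monotonically with the neighborhood size", {
  pair <- random_phantom_roi(99)
  t <- pair$tractogram
  idx <- build_point_index(t)
  st <- segment_stats(t)
  Ls <- seq(st$mean_len, st$max_len, length.out = 4)
  sets <- lapply(Ls, function(L) select_progressive(t, idx, pair$roi, L)$selected)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("disagreements with the uncompressed truth hug the ROI surface", {
  # after compression, brute force on the original and complete progressive
  # on the compressed tractogram may only disagree for streamlines whose
  # original polyline passes within met of the mesh
  met <- 0.4
  n_pairs <- 0L
  disagreement_dists <- numeric()
  for (seed in 31:42) {
    pair <- random_phantom_roi(seed)
    t0 <- pair$tractogram
    tc <- linearize_tractogram(t0, linearization_params(met, 10))$tractogram
    idx <- build_point_index(tc)
    sel0 <- brute_force_select(t0, pair$roi)
    selc <- select_progressive(tc, idx, pair$roi, "complete")$selected
    n_pairs <- n_pairs + 1L
    for (sid in union(setdiff(sel0, selc), setdiff(selc, sel0))) {
      disagreement_dists <- c(disagreement_dists,
                              min_dist_to_mesh(t0$streamlines[[sid]], pair$roi))
    }
  }
  expect_equal(n_pairs, 12L)
  # 0.05 allowance = half the distance oracle's polyline sampling spacing
  expect_true(all(disagreement_dists < met + 0.06))
})

test_that("each phase only touches points of its own box", {
  pair <- random_phantom_roi(7)
  t <- pair$tractogram
  idx <- build_point_index(t)
  res <- select_progressive(t, idx, pair$roi, "complete")
  all_pts <- do.call(rbind, t$streamlines)
  aabb <- pair$roi$aabb
  in_box <- function(P, lo, hi) {
    P[, 1] >= lo[1] & P[, 1] <= hi[1] & P[, 2] >= lo[2] & P[, 2] <= hi[2] &
      P[, 3] >= lo[3] & P[, 3] <= hi[3]
  }
  expect_equal(res$n_phase1_candidates, sum(in_box(all_pts, aabb[1, ], aabb[2, ])))
  L <- res$neighborhood_mm
  sid <- rep.int(seq_along(t$streamlines), vapply(t$streamlines, nrow, integer(1)))
  ext <- in_box(all_pts, aabb[1, ] - L, aabb[2, ] + L)
  expect_equal(res$n_phase2_candidates,
               sum(ext & !(sid %in% res$phase1_ids)))
})

test_that("missed fraction reproduces the printed selection percentages", {
  expect_equal(missed_fraction(1527, 1548), 1.36)
  expect_equal(missed_fraction(1605, 1655), 3.02)
  expect_equal(missed_fraction(1076, 1562), 31.11)
  expect_equal(missed_fraction(100, 100), 0)
  expect_error(missed_fraction(5, 0), "> 0")
  expect_error(missed_fraction(10, 5), "<=")
})

test_that("external OBJ and PLY meshes load as valid ROIs", {
  b <- box_roi(c(1, 2, 3), c(1, 1, 1))
  obj <- tempfile(fileext = ".obj")
  writeLines(c(
    apply(b$vertices, 1, function(v) sprintf("v %.9g %.9g %.9g", v[1], v[2], v[3])),
    apply(b$triangles, 1, function(f) sprintf("f %d %d %d", f[1], f[2], f[3]))
  ), obj)
  m <- read_mesh(obj)
  expect_equal(m$aabb, b$aabb)
  expect_true(point_in_mesh(c(1, 2, 3), m))

  ply <- tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(b$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(b$triangles)),
    "property list uchar int vertex_indices", "end_header",
    apply(b$vertices, 1, function(v) sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])),
    apply(b$triangles - 1L, 1, function(f) sprintf("3 %d %d %d", f[1], f[2], f[3]))
  ), ply)
  m2 <- read_mesh(ply)
  expect_equal(m2$aabb, b$aabb)
  expect_false(point_in_mesh(c(5, 5, 5), m2))
})
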
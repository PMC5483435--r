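test_that("segment traversal matches hand-worked grid walks", {
  expect_equal(traverse_segment(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5), c(4, 4, 4)),
               rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(2L, 0L, 0L)))
  # zero-length segment: its single containing voxel
  expect_equal(traverse_segment(c(1.2, 3.7, 0.1), c(1.2, 3.7, 0.1), c(4, 4, 4)),
               matrix(c(1L, 3L, 0L), 1))
  # diagonal: x crossing (t = 0.5) precedes y crossing (t = 2/3)
  expect_equal(traverse_segment(c(0.25, 0.5, 0.5), c(1.75, 1.25, 0.5), c(4, 4, 4)),
               rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L)))
  # out-of-grid portions are clipped away
  v <- traverse_segment(c(-1.5, 0.5, 0.5), c(2.5, 0.5, 0.5), c(4, 4, 4))
  expect_equal(v[, 1], 0:2)
})

test_that("traversal equals the supersampling oracle in generic position", {
  set.seed(101)
  dims <- c(12L, 12L, 12L)
  for (i in 1:400) {
    seg <- random_generic_segment(-1, 13, 5)
    got <- traverse_segment(seg$g0, seg$g1, dims)
    want <- supersample_voxels(seg$g0, seg$g1, dims)
    expect_equal(got, want)
  }
})

test_that("segment voxel sets contain point voxel sets", {
  ref <- identity_ref(c(10L, 10L, 10L))
  # 2-point streamline through 3 voxels: the corner/through case
  s <- rbind(c(0.2, 0.2, 0.2), c(2.2, 0.2, 0.2))
  expect_equal(nrow(streamline_voxels(s, ref, "point")), 2L)
  expect_equal(nrow(streamline_voxels(s, ref, "segment")), 3L)
  # wholly inside one voxel
  s1 <- rbind(c(3.1, 3.1, 3.1), c(3.3, 3.4, 3.2))
  expect_equal(streamline_voxels(s1, ref, "point"), matrix(3L, 1, 3))
  expect_equal(streamline_voxels(s1, ref, "segment"), matrix(3L, 1, 3))

  set.seed(55)
  for (i in 1:20) {
    s <- matrix(runif(30, 0.5, 9.5), ncol = 3)
    pv <- streamline_voxels(s, ref, "point")
    sv <- streamline_voxels(s, ref, "segment")
    expect_true(all(paste(pv[, 1], pv[, 2], pv[, 3]) %in%
                    paste(sv[, 1], sv[, 2], sv[, 3])))
  }
})

# insert the midpoint of every segment: same polyline, double the sampling
resample_collinear <- function(s) {
  n <- nrow(s)
  mid <- (s[-1, , drop = FALSE] + s[-n, , drop = FALSE]) / 2
  out <- matrix(0, 2 * n - 1, 3)
  out[seq(1, 2 * n - 1, by = 2), ] <- s
  out[seq(2, 2 * n - 2, by = 2), ] <- mid
  out
}

test_that("segment mapping is invariant under collinear resampling", {
  ref <- identity_ref(c(10L, 10L, 10L))
  set.seed(66)
  for (i in 1:10) {
    s <- matrix(runif(24, 0.5, 9.5), ncol = 3)
    s2 <- resample_collinear(s)
    key <- function(v) sort(paste(v[, 1], v[, 2], v[, 3]))
    expect_equal(key(streamline_voxels(s2, ref, "segment")),
                 key(streamline_voxels(s, ref, "segment")))
    # point mode picks up the midpoints' voxels
    expect_gte(nrow(streamline_voxels(s2, ref, "point")),
               nrow(streamline_voxels(s, ref, "point")))
  }
})

test_that("weight maps count streamlines or samples as requested", {
  ref <- identity_ref(c(10L, 10L, 10L))
  # 3 identical straight streamlines through 4 voxels
  s <- rbind(c(0.5, 0.5, 0.5), c(3.5, 0.5, 0.5))
  t3 <- tractogram(list(s, s, s), ref)
  w <- bundle_weight_map(t3, mode = "segment", weighting = "per_streamline")
  expect_equal(nrow(w$voxels), 4L)
  expect_true(all(w$weights == 3))

  # 5 points in one voxel: per_sample counts 5, per_streamline counts 1
  # (world x in [1.7, 2.3] all falls in grid voxel 2 after the +0.5 shift)
  s5 <- cbind(seq(1.7, 2.3, length.out = 5), 2, 2)
  t1 <- tractogram(list(s5), ref)
  ws <- bundle_weight_map(t1, mode = "point", weighting = "per_sample")
  wp <- bundle_weight_map(t1, mode = "point", weighting = "per_streamline")
  expect_equal(ws$weights, 5)
  expect_equal(wp$weights, 1)
})

test_that("per-sample point weights conserve the total point count", {
  t <- generate_bundle(phantom_spec("random_walk", n_streamlines = 5L,
                                    angular_jitter = 10, seed = 12L))
  w <- bundle_weight_map(t, mode = "point", weighting = "per_sample")
  expect_equal(sum(w$weights), n_points(t))
})

test_that("compression leaves segment-mode maps intact but erodes point maps", {
  ref <- identity_ref(c(40L, 10L, 10L))
  sl <- lapply(seq(3.2, 4.8, length.out = 8), function(y)
    cbind(seq(1, 38, by = 0.4), y, 5))
  t <- tractogram(sl, ref)
  tc <- linearize_tractogram(t, linearization_params(0.1, Inf))$tractogram
  key <- function(w) sort(paste(w$voxels[, 1], w$voxels[, 2], w$voxels[, 3],
                                w$weights))
  w_seg0 <- bundle_weight_map(t, mode = "segment")
  w_segc <- bundle_weight_map(tc, ref = ref, mode = "segment")
  expect_equal(key(w_segc), key(w_seg0))
  w_pt0 <- bundle_weight_map(t, mode = "point")
  w_ptc <- bundle_weight_map(tc, ref = ref, mode = "point")
  expect_lt(nrow(w_ptc$voxels), nrow(w_pt0$voxels))

  # difference maps: all-zero for segments, not for points
  dseg <- weight_difference_map(w_seg0, w_segc)
  expect_true(all(dseg$values == 0))
  dpt <- weight_difference_map(w_pt0, w_ptc)
  expect_gt(sum(dpt$values != 0), 0)
  # a removed voxel keeps its original weight in the difference
  expect_equal(sum(dpt$values), sum(w_pt0$weights) - sum(w_ptc$weights))
})

test_that("bundle summaries average binarized and weighted maps correctly", {
  ref <- identity_ref(c(10L, 10L, 10L))
  s <- rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5))
  t <- tractogram(list(s), ref)
  w <- bundle_weight_map(t, mode = "segment")
  const <- analytic_metric("constant", ref, value = 0.7)
  sm <- bundle_summary(w, const)
  expect_equal(sm$mean_binary, 0.7)
  expect_equal(sm$mean_weighted, 0.7)

  # the streamline's two voxels are (1,1,1) and (2,1,1) (0-based); value
  # them 0.2 (w=1) and 0.8 (w=3)
  vals <- array(0, dim = c(10, 10, 10))
  vals[2, 2, 2] <- 0.2
  vals[3, 2, 2] <- 0.8
  m <- metric_map(vals, ref)
  w2 <- w
  w2$weights <- c(1, 3)
  sm2 <- bundle_summary(w2, m)
  expect_equal(sm2$mean_binary, 0.5)
  expect_equal(sm2$mean_weighted, 0.65)
  expect_equal(sm2$n_voxels, 2L)

  ref8 <- spatial_reference(diag(c(2, 2, 2, 1)), c(10, 10, 10))
  s8 <- rbind(c(0, 0, 0), c(19, 0, 0))
  w8 <- bundle_weight_map(tractogram(list(s8), ref8), mode = "segment")
  sm8 <- bundle_summary(w8, analytic_metric("constant", ref8, value = 1))
  expect_equal(sm8$n_voxels, 10L)
  expect_equal(sm8$volume, 80)    # 10 voxels x 8 mm^3
})

test_that("the robustness statistic matches its printed example", {
  r <- robustness_statistic(0.55113, 0.55281)
  expect_equal(r$m_bc - r$m_b0, 0.00168, tolerance = 1e-12)
  expect_equal(round(100 * r$r, 1), 0.3)
  expect_equal(robustness_statistic(0.5, 0.5)$r, 0)
  expect_equal(robustness_statistic(0.5, 0.45)$r, 0.1)
  expect_error(robustness_statistic(0, 1), "nonzero")
})

test_that("NIfTI round trip preserves a metric map and its grid", {
  ref <- spatial_reference(diag(c(2, 2, 2, 1)), c(8L, 8L, 8L))
  m <- analytic_metric("axis_gradient", ref, axis = 2L)
  path <- tempfile(fileext = ".nii.gz")
  write_metric_map(m, path)
  m2 <- read_metric_map(path)
  expect_equal(m2$values, m$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m2$ref$affine, ref$affine, tolerance = 1e-6, ignore_attr = TRUE)
})
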
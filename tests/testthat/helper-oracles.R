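# Independent reference implementations used as oracles. These are written
# from the definitions, not from the package internals, and stay deliberately
# naive: explicit loops, projection-based distances, no spatial pruning.

identity_ref <- function(dims = c(10L, 10L, 10L)) {
  spatial_reference(diag(4), dims)
}

# Point-to-infinite-line distance via projection (not the cross product).
proj_line_dist <- function(p, a, b) {
  u <- (b - a) / sqrt(sum((b - a)^2))
  v <- p - a
  rej <- v - sum(v * u) * u
  sqrt(sum(rej^2))
}

# Naive greedy linearization, written independently: index loops throughout,
# projection-based distances, explicit case labels.
naive_linearize <- function(pts, met, mld) {
  met <- max(met, 1e-12)
  n <- nrow(pts)
  kept <- 1L
  last <- 1L
  cand <- 2L
  while (cand < n) {
    nxt <- cand + 1L
    case <- "A"
    if (sqrt(sum((pts[nxt, ] - pts[last, ])^2)) > mld) {
      case <- "C"
    } else {
      for (k in seq(last + 1L, nxt - 1L)) {
        if (proj_line_dist(pts[k, ], pts[last, ], pts[nxt, ]) > met) {
          case <- "B"
          break
        }
      }
    }
    if (case == "A") {
      cand <- nxt
    } else {
      kept <- c(kept, cand)
      last <- cand
      cand <- cand + 1L
    }
  }
  pts[c(kept, n), , drop = FALSE]
}

# Supersampling traversal oracle: flood the segment with evenly spaced
# samples, floor them, deduplicate consecutively. A straight segment never
# revisits a voxel, so consecutive dedup equals set dedup (order preserved).
supersample_voxels <- function(g0, g1, dims, n = 1e4) {
  tt <- seq(0, 1, length.out = n)
  P <- cbind(g0[1] + tt * (g1[1] - g0[1]),
             g0[2] + tt * (g1[2] - g0[2]),
             g0[3] + tt * (g1[3] - g0[3]))
  V <- floor(P)
  change <- c(TRUE, rowSums(abs(diff(V))) > 0)
  V <- V[change, , drop = FALSE]
  inb <- V[, 1] >= 0 & V[, 1] < dims[1] &
         V[, 2] >= 0 & V[, 2] < dims[2] &
         V[, 3] >= 0 & V[, 3] < dims[3]
  out <- V[inb, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

# Liang-Barsky slab clipping of a segment against an axis-aligned box.
slab_clip_hits_box <- function(p0, p1, lo, hi, eps = 1e-9) {
  d <- p1 - p0
  t0 <- 0
  t1 <- 1
  for (ax in 1:3) {
    if (d[ax] == 0) {
      if (p0[ax] < lo[ax] - eps || p0[ax] > hi[ax] + eps) return(FALSE)
    } else {
      ta <- (lo[ax] - p0[ax]) / d[ax]
      tb <- (hi[ax] - p0[ax]) / d[ax]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  t0 <= t1 + eps
}

# Minimal independent TCK reader: header line scan + one readBin.
naive_read_tck_counts <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ch <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (b == as.raw(10L)) break
      ch <- c(ch, b)
    }
    line <- rawToChar(ch)
    hdr <- c(hdr, line)
    if (line == "END") break
  }
  offset <- as.integer(sub("^file: \\. ", "", grep("^file:", hdr, value = TRUE)))
  seek(con, offset)
  vals <- readBin(con, "double", n = (file.size(path) - offset) / 4, size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  ends <- which(is.nan(m[, 1]) | is.infinite(m[, 1]))
  pts_per <- diff(c(0L, ends)) - 1L
  pts_per <- pts_per[seq_len(max(0L, length(ends) - 1L))]  # drop EOF marker
  list(n_streamlines = length(pts_per), points_per = pts_per)
}

# Small deterministic tractogram of hand-placed streamlines.
toy_tractogram <- function(ref = identity_ref()) {
  tractogram(list(
    rbind(c(1, 1, 1), c(2, 1.2, 1), c(3, 1, 1.5), c(4.5, 2, 2)),
    rbind(c(5, 5, 5), c(5.5, 5.5, 5.5), c(6, 6, 6)),
    rbind(c(2, 7, 2), c(2, 8, 3))
  ), ref)
}

# A random phantom/ROI pair lying inside the default grid, for completeness
# harnesses. The ROI is centered near a random point of the bundle so most
# pairs actually interact.
random_phantom_roi <- function(seed) {
  set.seed(seed)
  kind <- sample(c("straight", "arc", "random_walk"), 1)
  # 40 mm walks from the grid center cannot escape the 100 mm field of view
  spec <- phantom_spec(kind, n_streamlines = 10L, step = 0.5, length = 40,
                       angular_jitter = 12, cross_section = 3,
                       seed = seed + 1000L)
  t <- generate_bundle(spec)
  s <- t$streamlines[[sample(length(t$streamlines), 1)]]
  anchor <- s[sample(nrow(s), 1), ] + runif(3, -4, 4)
  roi <- if (runif(1) < 0.5) {
    box_roi(anchor, runif(3, 1.5, 4))
  } else {
    ellipsoid_roi(anchor, runif(3, 1.5, 4), subdivisions = 1L)
  }
  list(tractogram = t, roi = roi)
}

# Exact point-to-triangle distance: plane projection if the foot lies inside
# the triangle, otherwise the nearest edge.
pt_tri_dist <- function(P, v0, v1, v2) {
  e1 <- v1 - v0
  e2 <- v2 - v0
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  W <- sweep(P, 2, v0)
  dplane <- W %*% nrm
  proj <- W - dplane %*% t(nrm)
  d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
  pu <- proj %*% e1
  pv <- proj %*% e2
  det <- d11 * d22 - d12^2
  u <- (d22 * pu - d12 * pv) / det
  v <- (d11 * pv - d12 * pu) / det
  inside <- u >= 0 & v >= 0 & u + v <= 1
  d <- rep(Inf, nrow(P))
  d[inside] <- abs(dplane[inside])
  out <- which(!inside)
  if (length(out) > 0) {
    pt_seg <- function(Q, a, b) {
      ab <- b - a
      tt <- pmin(pmax(sweep(Q, 2, a) %*% ab / sum(ab^2), 0), 1)
      foot <- sweep(tt %*% t(ab), 2, a, "+")
      sqrt(rowSums((Q - foot)^2))
    }
    Q <- P[out, , drop = FALSE]
    d[out] <- pmin(pt_seg(Q, v0, v1), pt_seg(Q, v1, v2), pt_seg(Q, v2, v0))
  }
  d
}

# Minimum distance from a polyline to a mesh surface (0 if any sampled point
# is inside). The polyline is sampled every ~0.1 mm, so the result is exact
# up to that sampling resolution.
min_dist_to_mesh <- function(s, roi, spacing = 0.1) {
  samples <- list(s)
  for (i in seq_len(nrow(s) - 1)) {
    len <- sqrt(sum((s[i + 1, ] - s[i, ])^2))
    n <- max(2L, ceiling(len / spacing) + 1L)
    tt <- seq(0, 1, length.out = n)
    samples[[i + 1]] <- cbind(s[i, 1] + tt * (s[i + 1, 1] - s[i, 1]),
                              s[i, 2] + tt * (s[i + 1, 2] - s[i, 2]),
                              s[i, 3] + tt * (s[i + 1, 3] - s[i, 3]))
  }
  P <- do.call(rbind, samples)
  if (any(points_in_mesh(P, roi))) return(0)
  d <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(roi$triangles))) {
    tri <- roi$triangles[i, ]
    d <- pmin(d, pt_tri_dist(P, roi$vertices[tri[1], ],
                             roi$vertices[tri[2], ], roi$vertices[tri[3], ]))
  }
  min(d)
}

# Vectorized projection-based distance of the rows of P to the infinite
# line through a and b.
line_dist_many <- function(P, a, b) {
  u <- (b - a) / sqrt(sum((b - a)^2))
  V <- sweep(P, 2, a)
  along <- V %*% u
  rej <- V - along %*% t(u)
  sqrt(rowSums(rej^2))
}

# Sorted parameters at which a segment crosses integer grid planes.
crossing_params <- function(g0, g1) {
  ts <- c(0, 1)
  for (ax in 1:3) {
    d <- g1[ax] - g0[ax]
    if (d == 0) next
    lo <- ceiling(min(g0[ax], g1[ax]))
    hi <- floor(max(g0[ax], g1[ax]))
    if (lo <= hi) ts <- c(ts, (lo:hi - g0[ax]) / d)
  }
  sort(ts[ts >= 0 & ts <= 1])
}

# Random segment in generic position: consecutive plane crossings separated
# by more than min_gap in parameter, so a supersampling oracle with sample
# spacing below min_gap lands at least one sample in every traversed voxel.
random_generic_segment <- function(span_lo, span_hi, max_len, min_gap = 2.5e-4) {
  repeat {
    g0 <- runif(3, span_lo, span_hi)
    g1 <- g0 + runif(3, -max_len, max_len)
    ts <- crossing_params(g0, g1)
    if (length(ts) < 2 || min(diff(ts)) > min_gap) return(list(g0 = g0, g1 = g1))
  }
}
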
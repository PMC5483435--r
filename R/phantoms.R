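#' Synthetic bundle specification
#'
#' Describes a seeded synthetic streamline bundle. `straight` and `arc`
#' centerlines emulate deterministic tracking (smooth, low local curvature;
#' the arc stands in for high-curvature bundles such as the corpus
#' callosum, the straight line for the corticospinal tract). `random_walk`
#' emulates probabilistic tracking: a unit-speed walk whose direction turns
#' by a random angle at every step (folded-normal magnitude of the stated
#' standard deviation, uniformly random azimuth in the plane orthogonal to
#' the current direction). `helix` adds out-of-plane curvature.
#'
#' Individual streamlines are the centerline offset by a uniform random
#' point in the disk of radius `cross_section` orthogonal to the local
#' direction (random walks additionally draw independent turns per
#' streamline). Steps are exactly `step` mm long.
#'
#' The default step (0.5 mm) matches the tracking step size of the
#' reference acquisition; the default grid for [default_reference()] is
#' 50^3 voxels at 2 mm isotropic, the acquisition resolution.
#'
#' @param kind `"straight"`, `"arc"`, `"helix"` or `"random_walk"`.
#' @param n_streamlines number of streamlines (>= 1).
#' @param step step length, mm (> 0).
#' @param length centerline length, mm (straight / random_walk / helix).
#' @param radius curvature radius, mm (arc / helix).
#' @param arc_deg arc angle, degrees (arc).
#' @param pitch helix pitch per turn, mm (helix).
#' @param angular_jitter per-step direction change s.d., degrees (random_walk).
#' @param cross_section bundle cross-section disk radius, mm.
#' @param center bundle center in world mm.
#' @param seed integer RNG seed; identical specs and seeds give bit-identical
#'   bundles.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("straight", "arc", "helix", "random_walk"),
                         n_streamlines = 50L, step = 0.5, length = 60,
                         radius = 20, arc_deg = 180, pitch = 20,
                         angular_jitter = 10, cross_section = 2,
                         center = c(50, 50, 50), seed = 1L) {
  kind <- match.arg(kind)
  if (step <= 0) stop("'step' must be > 0", call. = FALSE)
  if (n_streamlines < 1L) stop("need at least one streamline", call. = FALSE)
  if (angular_jitter < 0) stop("'angular_jitter' must be >= 0", call. = FALSE)
  structure(list(kind = kind, n_streamlines = as.integer(n_streamlines),
                 step = step, length = length, radius = radius,
                 arc_deg = arc_deg, pitch = pitch,
                 angular_jitter = angular_jitter,
                 cross_section = cross_section,
                 center = as.numeric(center), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default grid reference for phantoms
#'
#' A 50 x 50 x 50 grid of 2 mm isotropic voxels with its first voxel center
#' at the world origin (world domain roughly \[-1, 99\] mm per axis).
#'
#' @param dims grid dimensions.
#' @param voxel voxel edge length, mm.
#' @return A [spatial_reference()].
#' @export
default_reference <- function(dims = c(50L, 50L, 50L), voxel = 2) {
  spatial_reference(diag(c(voxel, voxel, voxel, 1)), dims)
}

# Run fn under a local, restored RNG state seeded from `seed`.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic bundle
#'
#' Builds the bundle described by a [phantom_spec()] inside the given grid.
#' All geometry must lie strictly inside the grid (it errors out
#' otherwise, rather than clipping), every step is exactly `spec$step` mm,
#' and the output is bit-identical for identical spec and seed.
#'
#' @param spec a [phantom_spec()].
#' @param ref a [spatial_reference()]; default [default_reference()].
#' @return A [tractogram()].
#' @export
generate_bundle <- function(spec, ref = default_reference()) {
  with_seed(spec$seed, function() {
    streamlines <- lapply(seq_len(spec$n_streamlines), function(i) {
      offset <- disk_offset(spec$cross_section)
      switch(spec$kind,
        straight = straight_line(spec, offset),
        arc = arc_line(spec, offset),
        helix = helix_line(spec, offset),
        random_walk = random_walk_line(spec, offset))
    })
    t <- tractogram(streamlines, ref)
    g <- floor(world_to_grid(do.call(rbind, t$streamlines), ref))
    if (any(g < 0) || any(sweep(g, 2, ref$dims, ">=")))
      stop("phantom geometry exceeds the grid", call. = FALSE)
    t
  })
}

# Uniform point in the unit disk, scaled to radius r, as a (y, z) pair.
disk_offset <- function(r) {
  if (r <= 0) return(c(0, 0))
  rho <- r * sqrt(stats::runif(1))
  th <- stats::runif(1, 0, 2 * pi)
  c(rho * cos(th), rho * sin(th))
}

straight_line <- function(spec, offset) {
  n <- floor(spec$length / spec$step) + 1L
  x <- spec$center[1] - spec$length / 2 + (seq_len(n) - 1L) * spec$step
  cbind(x, spec$center[2] + offset[1], spec$center[3] + offset[2])
}

# Circular arc in the xy-plane, apex (midpoint of the arc) at the bundle
# center; chord steps of equal angle have exactly equal length.
arc_line <- function(spec, offset) {
  r <- spec$radius + offset[1]           # radial component of the offset
  half <- spec$arc_deg * pi / 360
  dtheta <- 2 * asin(spec$step / (2 * spec$radius))   # centerline step angle
  n <- floor(2 * half / dtheta) + 1L
  theta <- -((n - 1L) / 2) * dtheta + (seq_len(n) - 1L) * dtheta
  cx <- spec$center[1]
  cy <- spec$center[2] - spec$radius     # circle center, apex at bundle center
  cbind(cx + r * sin(theta), cy + r * cos(theta), spec$center[3] + offset[2])
}

helix_line <- function(spec, offset) {
  r <- spec$radius + offset[1]
  climb <- spec$pitch / (2 * pi)         # dz per radian
  speed0 <- sqrt(spec$radius^2 + climb^2)
  dtheta <- spec$step / speed0           # uniform step along the centerline
  n <- floor(spec$length / spec$step) + 1L
  theta <- (seq_len(n) - 1L) * dtheta
  z0 <- spec$center[3] - climb * theta[n] / 2 + offset[2]
  cbind(spec$center[1] - spec$radius + r * cos(theta),
        spec$center[2] + r * sin(theta),
        z0 + climb * theta)
}

random_walk_line <- function(spec, offset) {
  n <- floor(spec$length / spec$step) + 1L
  pts <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  pts[1, ] <- spec$center - c(spec$length / 2, 0, 0) + c(0, offset)
  sigma <- spec$angular_jitter * pi / 180
  for (i in seq_len(n - 1L)) {
    if (sigma > 0) {
      ang <- abs(stats::rnorm(1, 0, sigma))          # folded normal magnitude
      az <- stats::runif(1, 0, 2 * pi)
      # orthonormal frame around the current direction
      up <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      e1 <- cross3(dir, up); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- cross3(dir, e1)
      perp <- cos(az) * e1 + sin(az) * e2
      dir <- cos(ang) * dir + sin(ang) * perp
      dir <- dir / sqrt(sum(dir^2))
    }
    pts[i + 1L, ] <- pts[i, ] + spec$step * dir
  }
  pts
}

#' Analytic scalar map
#'
#' Closed-form scalar maps evaluated at voxel centers, standing in for
#' diffusion scalar volumes (FA, MD, AD, RD): a constant; a normalized
#' gradient along one grid axis (`(i + 0.5) / dim`, so a 10-voxel axis runs
#' 0.05 to 0.95); or the world-mm distance from a center, normalized to
#' `[0, 1]` over the grid.
#'
#' @param pattern `"constant"`, `"axis_gradient"` or `"radial"`.
#' @param ref a [spatial_reference()].
#' @param value constant value (pattern `"constant"`).
#' @param axis gradient axis, 1-3 (pattern `"axis_gradient"`).
#' @param center world-mm center (pattern `"radial"`; default grid center).
#' @return A [metric_map()].
#' @export
analytic_metric <- function(pattern = c("constant", "axis_gradient", "radial"),
                            ref = default_reference(), value = 0.7,
                            axis = 1L, center = NULL) {
  pattern <- match.arg(pattern)
  dims <- ref$dims
  vals <- switch(pattern,
    constant = array(value, dim = dims),
    axis_gradient = {
      idx <- slice.index(array(0, dims), axis) - 1L
      array((idx + 0.5) / dims[axis], dim = dims)
    },
    radial = {
      centers <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                                       j = seq_len(dims[2]) - 1L,
                                       k = seq_len(dims[3]) - 1L))
      world <- grid_to_world(centers + 0.5, ref)
      if (is.null(center))
        center <- colMeans(rbind(grid_to_world(c(0.5, 0.5, 0.5), ref),
                                 grid_to_world(dims - 0.5, ref)))
      d <- sqrt(rowSums(sweep(world, 2, as.numeric(center))^2))
      array(d / max(d), dim = dims)
    })
  metric_map(vals, ref)
}

#' Canonical test scenarios
#'
#' Two seeded scenario builders mirroring the anatomy used to study
#' selection robustness: `cc_like` is a high-curvature arc bundle
#' (corpus-callosum-like) with a 5 x 5 x 5 mm cubic ROI at the arc apex;
#' `cst_like` is a straight bundle (corticospinal-tract-like) with the same
#' cube midway along it. The metric is an axis gradient along the bundle's
#' main axis.
#'
#' @param name `"cc_like"` or `"cst_like"`.
#' @param seed integer seed.
#' @param n_streamlines bundle size.
#' @return A list with `tractogram`, `roi` ([roi_mesh()]), `metric`
#'   ([metric_map()]) and `ref`.
#' @export
canonical_scenario <- function(name = c("cc_like", "cst_like"), seed = 1L,
                           n_streamlines = 50L) {
  name <- match.arg(name)
  ref <- default_reference()
  if (name == "cc_like") {
    spec <- phantom_spec("arc", n_streamlines = n_streamlines, step = 0.5,
                         radius = 20, arc_deg = 180, cross_section = 2,
                         center = c(50, 50, 50), seed = seed)
    roi_center <- c(50, 50, 50)          # arc apex
  } else {
    # nearly straight: a 2 deg/step walk, not an exact line — an exact line
    # compresses onto a regular kept-point lattice, which is a synthetic
    # degeneracy real tracts do not have
    spec <- phantom_spec("random_walk", n_streamlines = n_streamlines,
                         step = 0.5, length = 60, angular_jitter = 2,
                         cross_section = 2, center = c(50, 50, 50), seed = seed)
    roi_center <- c(50, 50, 50)          # midway along the bundle
  }
  list(tractogram = generate_bundle(spec, ref),
       roi = box_roi(roi_center, c(2.5, 2.5, 2.5)),
       metric = analytic_metric("axis_gradient", ref, axis = 1L),
       ref = ref)
}
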
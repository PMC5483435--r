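#' Closed triangle-mesh region of interest
#'
#' ROIs are watertight, consistently oriented triangle meshes; boxes and
#' ellipsoids of any size and orientation are built by [box_roi()] and
#' [ellipsoid_roi()], and arbitrary closed surfaces can be loaded with
#' [read_mesh()]. Construction validates watertightness (every directed
#' edge used exactly once, and matched by its reverse) and records the
#' axis-aligned bounding box.
#'
#' @param vertices V x 3 numeric matrix (mm).
#' @param triangles F x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `roi_mesh` with fields `vertices`,
#'   `triangles` and `aabb` (2 x 3 matrix, rows = min/max corner).
#' @export
roi_mesh <- function(vertices, triangles) {
  vertices <- as_point_matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  if (anyNA(triangles) || any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range", call. = FALSE)
  edges <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  key <- paste(edges[, 1], edges[, 2])
  rkey <- paste(edges[, 2], edges[, 1])
  if (anyDuplicated(key) || !setequal(key, rkey))
    stop("mesh is not watertight / consistently oriented", call. = FALSE)
  aabb <- rbind(apply(vertices, 2, min), apply(vertices, 2, max))
  rownames(aabb) <- c("min", "max")
  structure(list(vertices = vertices, triangles = triangles, aabb = aabb),
            class = "roi_mesh")
}

#' @export
print.roi_mesh <- function(x, ...) {
  cat(sprintf("ROI mesh: %d vertices, %d triangles, aabb [%s] - [%s] mm\n",
              nrow(x$vertices), nrow(x$triangles),
              paste(signif(x$aabb[1, ], 4), collapse = ", "),
              paste(signif(x$aabb[2, ], 4), collapse = ", ")))
  invisible(x)
}

check_rotation <- function(rotation) {
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L)) ||
      max(abs(rotation %*% t(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    stop("'rotation' must be a 3x3 proper orthonormal matrix", call. = FALSE)
  rotation
}

#' Box-shaped ROI mesh
#'
#' @param center 3-vector (mm).
#' @param half_extents 3 positive half edge lengths (mm); a 5 x 5 x 5 mm
#'   cube has half extents `c(2.5, 2.5, 2.5)`.
#' @param rotation 3x3 proper orthonormal matrix (columns = box axes).
#' @return A watertight [roi_mesh()] of 8 vertices and 12 triangles.
#' @export
box_roi <- function(center, half_extents, rotation = diag(3)) {
  if (any(half_extents <= 0)) stop("half_extents must be positive", call. = FALSE)
  rotation <- check_rotation(rotation)
  signs <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                 c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  local <- sweep(signs, 2, as.numeric(half_extents), "*")
  verts <- sweep(local %*% t(rotation), 2, as.numeric(center), "+")
  tris <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
                c(1, 2, 6), c(1, 6, 5), c(3, 4, 8), c(3, 8, 7),
                c(1, 5, 8), c(1, 8, 4), c(2, 3, 7), c(2, 7, 6))
  roi_mesh(verts, tris)
}

#' Ellipsoid ROI mesh (subdivided icosphere)
#'
#' @param center 3-vector (mm).
#' @param radii 3 positive semi-axis lengths (mm).
#' @param rotation 3x3 proper orthonormal matrix (columns = semi-axes).
#' @param subdivisions icosahedron subdivision level; level `s` gives
#'   `20 * 4^s` triangles (default 2, i.e. 320).
#' @return A watertight [roi_mesh()].
#' @export
ellipsoid_roi <- function(center, radii, rotation = diag(3), subdivisions = 2L) {
  if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
  rotation <- check_rotation(rotation)
  sph <- icosphere(subdivisions)
  verts <- sweep(sph$vertices, 2, as.numeric(radii), "*")
  verts <- sweep(verts %*% t(rotation), 2, as.numeric(center), "+")
  roi_mesh(verts, sph$triangles)
}

# Unit icosphere: icosahedron refined by edge-midpoint subdivision, all
# vertices renormalized to the unit sphere. Midpoints are shared through an
# edge cache so the result stays watertight.
icosphere <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- cache[[k]]
      if (!is.null(id)) return(id)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      cache[[k]] <- id
      id
    }
    newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(4L * i - 3L):(4L * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  list(vertices = v, triangles = f)
}

# Fixed, irrationally oriented ray direction for parity tests, so that
# rays from grid-aligned points essentially never graze a mesh edge.
RAY_DIR <- c(0.5424414198514148, 0.6243192475199875, 0.5621587427687966)

# Inclusive tolerance (mm) at mesh faces: boundary contact counts as inside
# / intersecting, keeping point and segment tests consistent at the surface.
MESH_EPS <- 1e-9

#' Are points inside a closed mesh?
#'
#' Ray-parity inclusion test against a watertight mesh: a point is inside
#' when a ray from it crosses the surface an odd number of times. Boundary
#' contact (within 1e-9 mm of the surface) counts as inside.
#'
#' @param points n x 3 matrix or 3-vector (mm).
#' @param roi a [roi_mesh()].
#' @return Logical vector of length n.
#' @export
points_in_mesh <- function(points, roi) {
  P <- as_point_matrix(points)
  n <- nrow(P)
  crossings <- integer(n)
  on_surface <- logical(n)
  V <- roi$vertices
  Tr <- roi$triangles
  for (i in seq_len(nrow(Tr))) {
    v0 <- V[Tr[i, 1], ]; e1 <- V[Tr[i, 2], ] - v0; e2 <- V[Tr[i, 3], ] - v0
    h <- cross3(RAY_DIR, e2)
    a <- sum(e1 * h)
    if (abs(a) < 1e-14) next
    S <- sweep(P, 2, v0)
    u <- (S %*% h) / a
    Q <- cross3_rows(S, e1)
    vv <- (Q %*% RAY_DIR) / a
    t <- (Q %*% e2) / a
    bary_ok <- u >= -1e-12 & vv >= -1e-12 & (u + vv) <= 1 + 1e-12
    on_surface <- on_surface | as.vector(bary_ok & abs(t) <= MESH_EPS)
    crossings <- crossings + as.integer(bary_ok & t > MESH_EPS)
  }
  unname(on_surface | (crossings %% 2L == 1L))
}

#' @rdname points_in_mesh
#' @param p a single point (3-vector, mm).
#' @export
point_in_mesh <- function(p, roi) {
  as.logical(points_in_mesh(p, roi))[1L]
}

#' Does a segment touch a closed mesh?
#'
#' True iff the closed segment `p0 -> p1` intersects any triangle of the
#' mesh (Moller-Trumbore test with inclusive 1e-9 tolerance) or either
#' endpoint lies inside the mesh (a segment wholly inside crosses no face).
#'
#' @param p0,p1 segment endpoints (3-vectors, mm), `p0 != p1`.
#' @param roi a [roi_mesh()].
#' @return Logical scalar.
#' @export
segment_intersects_mesh <- function(p0, p1, roi) {
  if (all(p0 == p1)) stop("degenerate segment", call. = FALSE)
  segments_intersect_mesh(matrix(p0, 1L), matrix(p1, 1L), roi)[1L]
}

# Vectorized segment-vs-mesh: rows of P0/P1 are segment endpoints.
segments_intersect_mesh <- function(P0, P1, roi) {
  P0 <- as_point_matrix(P0)
  P1 <- as_point_matrix(P1)
  n <- nrow(P0)
  hit <- points_in_mesh(P0, roi) | points_in_mesh(P1, roi)
  if (all(hit)) return(hit)
  D <- P1 - P0
  seg_len <- sqrt(rowSums(D^2))
  eps_t <- MESH_EPS / pmax(seg_len, .Machine$double.eps)  # mm -> parameter units
  V <- roi$vertices
  Tr <- roi$triangles
  for (i in seq_len(nrow(Tr))) {
    todo <- which(!hit)
    if (length(todo) == 0L) break
    v0 <- V[Tr[i, 1], ]; e1 <- V[Tr[i, 2], ] - v0; e2 <- V[Tr[i, 3], ] - v0
    Dt <- D[todo, , drop = FALSE]
    H <- cross3_rows(Dt, e2)
    a <- H %*% e1
    S <- sweep(P0[todo, , drop = FALSE], 2, v0)
    u <- rowSums(S * H) / a
    Q <- cross3_rows(S, e1)
    vv <- rowSums(Dt * Q) / a
    t <- (Q %*% e2) / a
    ok <- abs(a) > 1e-14 &
      u >= -1e-12 & vv >= -1e-12 & (u + vv) <= 1 + 1e-12 &
      t >= -eps_t[todo] & t <= 1 + eps_t[todo]
    hit[todo[ok]] <- TRUE
  }
  hit
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product of matrix rows with a fixed 3-vector.
cross3_rows <- function(A, b) {
  cbind(A[, 2] * b[3] - A[, 3] * b[2],
        A[, 3] * b[1] - A[, 1] * b[3],
        A[, 1] * b[2] - A[, 2] * b[1])
}

#' Read a triangle mesh from OBJ or PLY (ASCII)
#'
#' Minimal readers for the two interchange formats: Wavefront OBJ (`v` and
#' triangular `f` records) and ASCII PLY (vertex x/y/z properties and
#' triangular face lists). The loaded mesh must be closed; validation is the
#' same as [roi_mesh()].
#'
#' @param path file path (`.obj` or `.ply`).
#' @return A [roi_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") read_obj(lines) else if (ext == "ply") read_ply(lines)
  else stop("unsupported mesh format: ", ext, call. = FALSE)
}

read_obj <- function(lines) {
  toks <- strsplit(trimws(lines), "\\s+")
  vs <- do.call(rbind, lapply(toks[vapply(toks, function(x) length(x) > 0 && x[1] == "v", logical(1))],
                              function(x) as.numeric(x[2:4])))
  fs <- do.call(rbind, lapply(toks[vapply(toks, function(x) length(x) > 0 && x[1] == "f", logical(1))],
                              function(x) {
                                idx <- as.integer(sub("/.*", "", x[-1]))
                                if (length(idx) != 3L) stop("non-triangular OBJ face", call. = FALSE)
                                idx
                              }))
  if (is.null(vs) || is.null(fs)) stop("unreadable OBJ mesh", call. = FALSE)
  roi_mesh(vs, fs)
}

read_ply <- function(lines) {
  if (length(lines) == 0L || lines[1] != "ply") stop("unreadable PLY mesh", call. = FALSE)
  end_hdr <- match("end_header", lines)
  if (is.na(end_hdr)) stop("unreadable PLY mesh (no end_header)", call. = FALSE)
  hdr <- lines[seq_len(end_hdr)]
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("unreadable PLY mesh (element counts)", call. = FALSE)
  body <- lines[(end_hdr + 1L):length(lines)]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vs <- do.call(rbind, lapply(vtok, function(x) as.numeric(x[1:3])))
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  fs <- do.call(rbind, lapply(ftok, function(x) {
    if (as.integer(x[1]) != 3L) stop("non-triangular PLY face", call. = FALSE)
    as.integer(x[2:4]) + 1L
  }))
  roi_mesh(vs, fs)
}
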
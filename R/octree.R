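#' Octree point index over a tractogram
#'
#' Spatial index of every streamline point, supporting exact axis-aligned
#' box range queries. Each indexed item is a (streamline id, point index)
#' pair. Nodes split into octants when they exceed `leaf_capacity`, down to
#' `max_depth`; a point lying exactly on an internal split plane goes to the
#' lower child, which makes the tree deterministic.
#'
#' @param t a nonempty [tractogram()].
#' @param leaf_capacity maximum points per leaf before splitting (default 64).
#' @param max_depth maximum tree depth (default 10).
#' @return An object of class `point_index`.
#' @export
build_point_index <- function(t, leaf_capacity = 64L, max_depth = 10L) {
  if (!inherits(t, "tractogram")) stop("'t' must be a tractogram", call. = FALSE)
  if (length(t$streamlines) == 0L) stop("empty tractogram", call. = FALSE)
  pts <- do.call(rbind, t$streamlines)
  nper <- vapply(t$streamlines, nrow, integer(1))
  sid <- rep.int(seq_along(t$streamlines), nper)
  pidx <- unlist(lapply(nper, seq_len), use.names = FALSE)
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  root <- octree_build(pts, seq_len(nrow(pts)), lo, hi,
                       as.integer(leaf_capacity), as.integer(max_depth), 0L)
  structure(list(points = pts, sid = sid, pidx = pidx, root = root,
                 leaf_capacity = as.integer(leaf_capacity),
                 max_depth = as.integer(max_depth)),
            class = "point_index")
}

#' @export
print.point_index <- function(x, ...) {
  cat("Octree point index:", nrow(x$points), "points, leaf capacity",
      x$leaf_capacity, "\n")
  invisible(x)
}

octree_build <- function(pts, ids, lo, hi, cap, max_depth, depth) {
  if (length(ids) <= cap || depth >= max_depth)
    return(list(lo = lo, hi = hi, ids = ids, children = NULL))
  mid <- (lo + hi) / 2
  # octant 1..8; coordinates strictly above the split plane go up,
  # coordinates on the plane stay in the lower child
  oct <- 1L +
    (pts[ids, 1] > mid[1]) +
    2L * (pts[ids, 2] > mid[2]) +
    4L * (pts[ids, 3] > mid[3])
  children <- vector("list", 8L)
  for (o in seq_len(8L)) {
    cid <- ids[oct == o]
    if (length(cid) == 0L) next
    bit <- c((o - 1L) %% 2L, (o - 1L) %/% 2L %% 2L, (o - 1L) %/% 4L)
    clo <- ifelse(bit == 1L, mid, lo)
    chi <- ifelse(bit == 1L, hi, mid)
    children[[o]] <- octree_build(pts, cid, clo, chi, cap, max_depth, depth + 1L)
  }
  list(lo = lo, hi = hi, ids = NULL, children = children)
}

#' Range query on a point index
#'
#' Returns every indexed point inside a closed axis-aligned box, exactly as
#' a brute-force point-in-box scan would.
#'
#' @param idx a [build_point_index()] result.
#' @param lo,hi box corners (3-vectors, mm), inclusive on both sides.
#' @return A list with `sid`, `pidx` (integer vectors) and `points`
#'   (n x 3 matrix).
#' @export
query_point_index <- function(idx, lo, hi) {
  ids <- octree_query(idx$root, idx$points, as.numeric(lo), as.numeric(hi))
  list(sid = idx$sid[ids], pidx = idx$pidx[ids],
       points = idx$points[ids, , drop = FALSE])
}

octree_query <- function(node, pts, lo, hi) {
  if (is.null(node)) return(integer())
  if (any(node$hi < lo) || any(node$lo > hi)) return(integer())
  if (is.null(node$children)) {
    ids <- node$ids
    if (length(ids) == 0L) return(integer())
    P <- pts[ids, , drop = FALSE]
    inside <- P[, 1] >= lo[1] & P[, 1] <= hi[1] &
              P[, 2] >= lo[2] & P[, 2] <= hi[2] &
              P[, 3] >= lo[3] & P[, 3] <= hi[3]
    return(ids[inside])
  }
  unlist(lapply(node$children, octree_query, pts = pts, lo = lo, hi = hi),
         use.names = FALSE)
}
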
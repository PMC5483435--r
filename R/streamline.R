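#' Validate a streamline
#'
#' A streamline is an ordered 3D polyline in world millimeters, stored as an
#' n x 3 numeric matrix. Validation enforces the polyline contract: at least
#' two points, every coordinate finite, and no two consecutive points
#' identical. Consecutive duplicates are removed (they create zero-length
#' segments, which break distance and voxel-traversal arithmetic); a
#' streamline reduced below two points is rejected.
#'
#' @param points n x 3 numeric matrix (or 3-vector rows coercible to one).
#' @param dedup_tol consecutive points closer than this (mm) are collapsed.
#' @return The validated n x 3 matrix.
#' @export
streamline <- function(points, dedup_tol = 0) {
  pts <- as_point_matrix(points)
  if (!all(is.finite(pts))) stop("streamline has non-finite coordinates", call. = FALSE)
  if (nrow(pts) >= 2L) {
    step2 <- rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)
    keep <- c(TRUE, step2 > dedup_tol^2)
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 2L)
    stop("streamline must have at least 2 distinct points", call. = FALSE)
  pts
}

#' Construct a tractogram
#'
#' A tractogram is a collection of streamlines sharing one spatial
#' reference; all coordinates are world RAS millimeters. Streamlines with
#' fewer than two distinct points are rejected; consecutive duplicate points
#' are dropped with a warning.
#'
#' @param streamlines list of n x 3 matrices (world mm).
#' @param ref a [spatial_reference()].
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, ref) {
  if (!inherits(ref, "spatial_reference"))
    stop("'ref' must be a spatial_reference", call. = FALSE)
  if (!is.list(streamlines)) stop("'streamlines' must be a list", call. = FALSE)
  n_before <- vapply(streamlines, function(s) nrow(as_point_matrix(s)), integer(1))
  streamlines <- lapply(streamlines, streamline)
  n_after <- vapply(streamlines, nrow, integer(1))
  if (any(n_after < n_before))
    warning(sum(n_before - n_after), " consecutive duplicate point(s) removed",
            call. = FALSE)
  structure(list(streamlines = streamlines, ref = ref), class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- n_points(x)
  cat("Tractogram:", length(x$streamlines), "streamline(s),", np, "points\n")
  print(x$ref)
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Total point count of a tractogram
#' @param t a [tractogram()].
#' @return Integer total number of points.
#' @export
n_points <- function(t) {
  if (length(t$streamlines) == 0L) return(0L)
  sum(vapply(t$streamlines, nrow, integer(1)))
}

#' Segment length statistics of a tractogram
#'
#' Exact maximum and mean Euclidean length (mm) over every consecutive-point
#' segment of every streamline. The maximum drives the exact extended
#' neighborhood of progressive selection; the mean drives the faster,
#' possibly incomplete heuristic.
#'
#' @param t a [tractogram()] with at least one streamline.
#' @return A list with class `segment_stats`: `max_len`, `mean_len` (mm) and
#'   `n_segments`.
#' @examples
#' ref <- spatial_reference(diag(4), c(10, 10, 10))
#' t <- tractogram(list(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))), ref)
#' segment_stats(t)
#' @export
segment_stats <- function(t) {
  if (!inherits(t, "tractogram")) stop("'t' must be a tractogram", call. = FALSE)
  if (length(t$streamlines) == 0L) stop("empty tractogram", call. = FALSE)
  lens <- unlist(lapply(t$streamlines, segment_lengths), use.names = FALSE)
  structure(list(max_len = max(lens), mean_len = mean(lens),
                 n_segments = length(lens)),
            class = "segment_stats")
}

#' @export
print.segment_stats <- function(x, ...) {
  cat(sprintf("Segments: n = %d, max = %.4g mm, mean = %.4g mm\n",
              x$n_segments, x$max_len, x$mean_len))
  invisible(x)
}

# Euclidean lengths of the consecutive segments of one streamline.
segment_lengths <- function(pts) {
  d <- pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  sqrt(rowSums(d^2))
}
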
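#' Spatial reference for a voxel grid
#'
#' Ties world space (RAS millimeters) to a voxel grid. The affine maps a
#' 0-based voxel index, taken at the voxel *center*, to world mm — the NIfTI
#' convention. Internally a half-voxel shift turns this into the half-open
#' cube convention used by all grid algorithms: voxel `(i,j,k)` occupies
#' `[i,i+1) x [j,j+1) x [k,k+1)` in continuous grid coordinates, so
#' `floor()` of a grid coordinate is the containing voxel.
#'
#' @param affine 4x4 numeric matrix, voxel-center index to world mm.
#' @param dims integer vector of 3 positive grid dimensions.
#' @param voxel_sizes optional numeric vector of 3 voxel edge lengths (mm);
#'   derived from the affine columns when omitted, and validated against
#'   them (1e-4 relative tolerance) when given.
#' @return An object of class `spatial_reference`.
#' @examples
#' ref <- spatial_reference(diag(4), c(10, 10, 10))
#' ref$voxel_sizes
#' @export
spatial_reference <- function(affine, dims, voxel_sizes = NULL) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("'affine' is singular", call. = FALSE)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("'dims' must be 3 positive integers", call. = FALSE)
  col_norms <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (is.null(voxel_sizes)) {
    voxel_sizes <- col_norms
  } else {
    voxel_sizes <- as.numeric(voxel_sizes)
    if (length(voxel_sizes) != 3L || any(voxel_sizes <= 0))
      stop("'voxel_sizes' must be 3 positive lengths", call. = FALSE)
    if (any(abs(voxel_sizes - col_norms) > 1e-4 * col_norms))
      stop("'voxel_sizes' disagree with the affine column norms", call. = FALSE)
  }
  structure(
    list(affine = affine, dims = dims, voxel_sizes = voxel_sizes,
         inverse = solve(affine)),
    class = "spatial_reference"
  )
}

#' @export
print.spatial_reference <- function(x, ...) {
  cat("Spatial reference:", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$voxel_sizes, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' World to continuous grid coordinates
#'
#' Maps world-mm points to continuous grid coordinates under the half-open
#' cube convention: the containing voxel of a point is `floor(world_to_grid(p))`
#' (0-based), with the lower cube face inclusive and the upper exclusive.
#' With an identity affine the world origin sits at the center of voxel
#' `(0,0,0)` and maps to grid `(0.5, 0.5, 0.5)`.
#'
#' @param points numeric matrix (n x 3) or length-3 vector of world mm.
#' @param ref a [spatial_reference()].
#' @return An n x 3 matrix of continuous grid coordinates.
#' @seealso [grid_to_world()]
#' @export
world_to_grid <- function(points, ref) {
  pts <- as_point_matrix(points)
  if (!all(is.finite(pts))) stop("non-finite coordinates", call. = FALSE)
  g <- sweep(pts %*% t(ref$inverse[1:3, 1:3]), 2, ref$inverse[1:3, 4], "+")
  g + 0.5
}

#' Continuous grid to world coordinates
#'
#' Inverse of [world_to_grid()]: grid coordinate `(i+0.5, j+0.5, k+0.5)`
#' maps to the world-mm center of voxel `(i,j,k)`.
#'
#' @inheritParams world_to_grid
#' @param points numeric matrix (n x 3) or length-3 vector of continuous
#'   grid coordinates.
#' @return An n x 3 matrix of world mm.
#' @export
grid_to_world <- function(points, ref) {
  g <- as_point_matrix(points) - 0.5
  sweep(g %*% t(ref$affine[1:3, 1:3]), 2, ref$affine[1:3, 4], "+")
}

# Coerce a 3-vector or n x 3 matrix to an n x 3 double matrix.
as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("points must be 3D", call. = FALSE)
    points <- matrix(as.numeric(points), nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns", call. = FALSE)
  storage.mode(points) <- "double"
  points
}
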
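#' Scalar metric map on a voxel grid
#'
#' Wraps a 3D scalar grid (e.g. FA, MD) together with its spatial reference.
#'
#' @param values 3D numeric array; dimensions must equal `ref$dims`.
#' @param ref a [spatial_reference()].
#' @return An object of class `metric_map`.
#' @export
metric_map <- function(values, ref) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == ref$dims))
    stop("metric dimensions do not match the reference grid", call. = FALSE)
  if (!all(is.finite(values))) stop("metric map has non-finite values", call. = FALSE)
  structure(list(values = values, ref = ref), class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("Metric map: %s voxels, range [%.4g, %.4g]\n",
              paste(x$ref$dims, collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read a scalar map from NIfTI
#'
#' @param path NIfTI file (.nii / .nii.gz).
#' @return A [metric_map()] whose reference carries the NIfTI sform/qform
#'   affine (voxel-center to world RAS mm).
#' @export
read_metric_map <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  metric_map(vals, spatial_reference(aff, dim(vals)))
}

#' Write a scalar map (or weight/difference grid) to NIfTI
#'
#' @param m a [metric_map()] or any object with `values` and `ref` fields.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_metric_map <- function(m, path) {
  img <- RNifti::asNifti(m$values)
  img <- RNifti::`sform<-`(img, structure(m$ref$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
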
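# NIfTI-1 I/O. All on-disk images use the canonical RAS orientation:
# +x = left-right (LR), +y = anterior-posterior (AP), +z = cranio-caudal (CC).
# Files in another orientation are reoriented on read (scalar volumes) so the
# in-memory convention is always (LR, AP, CC).

geometry_from_nifti <- function(img) {
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    vvh_validation_error("zero or negative spacing in NIfTI header: (%s)",
                         paste(format(spacing), collapse = ", "))
  grid_geometry(dim(img)[1:3], spacing = spacing, origin = xf[1:3, 4])
}

nifti_from_geometry <- function(values, geometry) {
  img <- RNifti::asNifti(values)
  nd <- length(dim(values))
  RNifti::pixdim(img) <- c(geometry$spacing, rep(1, nd - 3L))
  affine <- diag(4)
  diag(affine)[1:3] <- geometry$spacing
  affine[1:3, 4] <- geometry$origin
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

canonicalise <- function(img) {
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  img
}

#' Read a scalar volume from a NIfTI-1 file
#'
#' Axes are reoriented to the canonical (LR, AP, CC) = RAS order, spacing is
#' taken from the header in mm, and the origin is the world position of voxel
#' (0,0,0). Integer-valued data round-trip losslessly.
#'
#' @param path path to a 3D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    vvh_io_error("file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    vvh_validation_error("non-3D payload: expected a 3D scalar volume, got %dD",
                         length(dim(img)))
  img <- canonicalise(img)
  vals <- array(as.numeric(img), dim = dim(img))
  if (anyNA(vals) || !all(is.finite(vals)))
    vvh_validation_error("volume %s contains non-finite values", path)
  volume3d(vals, geometry_from_nifti(img))
}

#' Write a scalar volume to a NIfTI-1 file
#'
#' @param vol a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`); parent must be writable.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "volume3d"))
    vvh_validation_error("vol must be a volume3d")
  if (anyNA(vol$values) || !all(is.finite(vol$values)))
    vvh_validation_error("refusing to write volume with non-finite values")
  if (!dir.exists(dirname(path)))
    vvh_io_error("directory not writable: %s", dirname(path))
  RNifti::writeNifti(nifti_from_geometry(vol$values, vol$geometry), path)
  invisible(path)
}

#' Read a binary structure mask from a NIfTI-1 file
#'
#' Any nonzero label is treated as structure membership.
#'
#' @param path path to a 3D integer-label NIfTI-1 file.
#' @return a [label_mask()].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  label_mask(array(vol$values != 0, dim = vol$geometry$shape), vol$geometry)
}

#' Write a binary structure mask to a NIfTI-1 file
#'
#' @param mask a [label_mask()]; written as 0/1 labels.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "label_mask"))
    vvh_validation_error("mask must be a label_mask")
  vals <- array(as.integer(mask$membership), dim = mask$geometry$shape)
  write_volume(volume3d(vals, mask$geometry), path)
}

#' Read a displacement vector field from a 4D NIfTI-1 file
#'
#' The file must be 4D with exactly 3 components on the last axis, stored in
#' the canonical (LR, AP, CC) component order with values in mm.
#'
#' @param path path to a 4D NIfTI-1 file.
#' @return a [displacement_field()].
#' @export
read_displacement_field <- function(path) {
  if (!file.exists(path))
    vvh_io_error("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    vvh_validation_error("displacement field must be a 4D NIfTI, got %dD",
                         length(d))
  if (d[4L] != 3L)
    vvh_validation_error("wrong component count: expected 3 components, got %d",
                         d[4L])
  if (!identical(RNifti::orientation(img), "RAS"))
    vvh_validation_error(
      "displacement fields must be stored in canonical RAS orientation")
  arr <- array(as.numeric(img), dim = d)
  if (anyNA(arr) || !all(is.finite(arr)))
    vvh_validation_error("displacement field %s contains non-finite values", path)
  geom <- grid_geometry(d[1:3], spacing = RNifti::pixdim(img)[1:3],
                        origin = RNifti::xform(img)[1:3, 4])
  field_from_array(arr, geom)
}

#' Write a displacement vector field to a 4D NIfTI-1 file
#'
#' @param field a [displacement_field()]; stored as a 4D image with the
#'   (LR, AP, CC) components in mm on the last axis.
#' @param path output path.
#' @export
write_displacement_field <- function(field, path) {
  if (!inherits(field, "displacement_field"))
    vvh_validation_error("field must be a displacement_field")
  if (!dir.exists(dirname(path)))
    vvh_io_error("directory not writable: %s", dirname(path))
  RNifti::writeNifti(
    nifti_from_geometry(field_as_array(field), field$geometry), path)
  invisible(path)
}
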
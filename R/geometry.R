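#' @useDynLib vvhmotion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Condition helpers: every user-facing failure is a classed condition so the
# CLI can map validation errors to exit code 2 and I/O errors to exit code 1.
vvh_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "vvh_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

vvh_validation_error <- function(msg, ...) vvh_stop("vvh_validation_error", msg, ...)
vvh_io_error <- function(msg, ...) vvh_stop("vvh_io_error", msg, ...)

#' Grid geometry of a volume on anatomical axes
#'
#' Describes the voxel grid every container in the package lives on: voxel
#' counts, voxel spacing in mm, and the world position (mm) of the centre of
#' voxel (0,0,0). Axes are always stored in canonical (LR, AP, CC) order:
#' axis 1 is left-right, axis 2 anterior-posterior, axis 3 cranio-caudal.
#' Voxel indices are 0-based and a voxel's world position is its centre.
#'
#' @param shape integer vector of length 3, voxels per axis (LR, AP, CC).
#' @param spacing numeric length 3, mm per voxel per axis; strictly positive.
#' @param origin numeric length 3, mm position of the centre of voxel (0,0,0).
#' @return an object of class `grid_geometry`.
#' @export
#' @examples
#' g <- grid_geometry(c(96, 96, 120), spacing = c(1.25, 1.25, 1.25))
#' world_coordinates(g, c(0, 0, 16))
grid_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    vvh_validation_error("grid geometry requires 3 axes (LR, AP, CC)")
  if (any(is.na(shape)) || any(shape < 1L))
    vvh_validation_error("all voxel counts must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    vvh_validation_error("all spacings must be strictly positive, got (%s)",
                         paste(format(spacing), collapse = ", "))
  if (any(!is.finite(origin)))
    vvh_validation_error("origin must be finite")
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         axis_labels = c("LR", "AP", "CC")),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

geometry_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stopifnot_same_geometry <- function(a, b, what = "inputs") {
  if (!geometry_equal(a$geometry, b$geometry))
    vvh_validation_error("%s must share one grid geometry", what)
  invisible(TRUE)
}

#' World coordinates of a voxel centre
#'
#' @param geometry a [grid_geometry()].
#' @param voxel_index integer vector of length 3, 0-based (LR, AP, CC).
#' @return numeric length 3: `origin + voxel_index * spacing` in mm.
#' @export
world_coordinates <- function(geometry, voxel_index) {
  idx <- as.numeric(voxel_index)
  if (length(idx) != 3L || any(!is.finite(idx)))
    vvh_validation_error("voxel_index must be a finite integer triple")
  if (any(idx != floor(idx)))
    vvh_validation_error("voxel_index must be whole numbers")
  if (any(idx < 0) || any(idx > geometry$shape - 1L))
    vvh_validation_error("voxel_index (%s) out of bounds for shape (%s)",
                         paste(idx, collapse = ","),
                         paste(geometry$shape, collapse = ","))
  geometry$origin + idx * geometry$spacing
}

#' Scalar 3D volume
#'
#' A scalar image (HU-like intensities) on a [grid_geometry()].
#'
#' @param values numeric 3D array matching `geometry$shape`; all finite.
#' @param geometry a [grid_geometry()].
#' @return an object of class `volume3d` with fields `values`, `geometry`.
#' @export
volume3d <- function(values, geometry) {
  if (!is.array(values) || length(dim(values)) != 3L)
    vvh_validation_error("values must be a 3D array")
  if (!identical(as.integer(dim(values)), geometry$shape))
    vvh_validation_error("values shape (%s) does not match geometry (%s)",
                         paste(dim(values), collapse = "x"),
                         paste(geometry$shape, collapse = "x"))
  if (anyNA(values) || !all(is.finite(values)))
    vvh_validation_error("volume contains non-finite values")
  structure(list(values = values, geometry = geometry), class = "volume3d")
}

#' Binary structure mask
#'
#' Voxel membership of a delineated structure (e.g. a gross tumor volume).
#' A voxel belongs to the structure iff its centre lies inside it; each
#' member voxel carries equal volume weight `prod(spacing)` mm^3.
#'
#' @param membership logical 3D array matching `geometry$shape`.
#' @param geometry a [grid_geometry()].
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(membership, geometry) {
  if (!is.array(membership) || length(dim(membership)) != 3L)
    vvh_validation_error("membership must be a 3D array")
  storage.mode(membership) <- "logical"
  if (anyNA(membership))
    vvh_validation_error("mask contains NA membership")
  if (!identical(as.integer(dim(membership)), geometry$shape))
    vvh_validation_error("mask shape does not match geometry")
  structure(list(membership = membership, geometry = geometry),
            class = "label_mask")
}

mask_count <- function(mask) sum(mask$membership)

#' Dense displacement vector field
#'
#' Per-voxel displacement in mm on the fixed-image grid, split into the
#' anatomical components `u_LR`, `u_AP`, `u_CC`. The field is pull-back
#' (fixed-to-moving): it maps each fixed-image voxel centre to the position
#' of the same anatomy in the moving image. Components are stored signed;
#' absolute values are taken only at analysis time.
#'
#' @param u_lr,u_ap,u_cc numeric 3D arrays matching `geometry$shape`, mm.
#' @param geometry a [grid_geometry()] (the fixed-image grid).
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(u_lr, u_ap, u_cc, geometry) {
  for (comp in list(u_lr, u_ap, u_cc)) {
    if (!is.array(comp) || length(dim(comp)) != 3L ||
        !identical(as.integer(dim(comp)), geometry$shape))
      vvh_validation_error("each displacement component must match geometry shape")
    if (anyNA(comp) || !all(is.finite(comp)))
      vvh_validation_error("displacement field contains non-finite values")
  }
  structure(list(u_lr = u_lr, u_ap = u_ap, u_cc = u_cc, geometry = geometry),
            class = "displacement_field")
}

# Stack components into an (nx, ny, nz, 3) array (LR, AP, CC on the 4th axis).
field_as_array <- function(field) {
  d <- field$geometry$shape
  arr <- array(0, c(d, 3L))
  arr[, , , 1L] <- field$u_lr
  arr[, , , 2L] <- field$u_ap
  arr[, , , 3L] <- field$u_cc
  arr
}

field_from_array <- function(arr, geometry) {
  displacement_field(
    u_lr = array(arr[, , , 1L], dim = geometry$shape),
    u_ap = array(arr[, , , 2L], dim = geometry$shape),
    u_cc = array(arr[, , , 3L], dim = geometry$shape),
    geometry = geometry
  )
}
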
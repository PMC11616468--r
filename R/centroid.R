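#' Centre of mass of a structure mask
#'
#' Unweighted mean of the world coordinates of the member-voxel centres.
#'
#' @param mask a nonempty [label_mask()].
#' @return numeric length 3, mm on the (LR, AP, CC) axes.
#' @export
centroid <- function(mask) {
  if (!inherits(mask, "label_mask"))
    vvh_validation_error("mask must be a label_mask")
  if (!any(mask$membership))
    vvh_validation_error("empty mask: centroid undefined")
  idx <- which(mask$membership, arr.ind = TRUE) - 1  # 0-based voxel indices
  g <- mask$geometry
  unname(g$origin + colMeans(idx) * g$spacing)
}

#' Centroid displacement between two phases
#'
#' The classical point-based motion baseline: the difference of the
#' structure's centre of mass between a fixed (e.g. inhalation) and moving
#' (e.g. exhalation) delineation, per axis and as the 3D Euclidean norm.
#'
#' @param mask_fixed,mask_moving nonempty [label_mask()] objects on the same
#'   grid.
#' @return an object of class `centroid_result`: list with signed `d_LR`,
#'   `d_AP`, `d_CC` (mm, moving minus fixed) and nonnegative `d_3D`.
#' @export
centroid_displacement <- function(mask_fixed, mask_moving) {
  stopifnot_same_geometry(mask_fixed, mask_moving, "the two masks")
  d <- centroid(mask_moving) - centroid(mask_fixed)
  structure(
    list(d_LR = d[[1]], d_AP = d[[2]], d_CC = d[[3]],
         d_3D = sqrt(sum(d^2))),
    class = "centroid_result"
  )
}

#' @export
print.centroid_result <- function(x, ...) {
  cat(sprintf("centroid displacement: LR %.3f, AP %.3f, CC %.3f, 3D %.3f mm\n",
              x$d_LR, x$d_AP, x$d_CC, x$d_3D))
  invisible(x)
}
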
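#' Admissible analysis directions
#'
#' Per-voxel displacement lengths can be measured along a single anatomical
#' axis (`"LR"`, `"AP"`, `"CC"`) or as the 3D Euclidean vector magnitude
#' (`"VEC3D"`).
#'
#' @export
VVH_DIRECTIONS <- c("LR", "AP", "CC", "VEC3D")

match_direction <- function(direction) {
  d <- toupper(as.character(direction))
  d[d %in% c("3D", "VECTOR", "VEC")] <- "VEC3D"
  if (length(d) != 1L || !d %in% VVH_DIRECTIONS)
    vvh_validation_error("direction must be one of %s",
                         paste(VVH_DIRECTIONS, collapse = ", "))
  d
}

#' Per-voxel displacement lengths of a structure
#'
#' Restricts a displacement field to the voxels of a structure mask and
#' returns one nonnegative length per member voxel: `|u_axis|` for a single
#' direction, or `sqrt(u_LR^2 + u_AP^2 + u_CC^2)` for the 3D vector.
#'
#' @param field a [displacement_field()].
#' @param mask a [label_mask()] on the same grid; must be nonempty.
#' @param direction one of `"LR"`, `"AP"`, `"CC"`, `"VEC3D"`.
#' @return an object of class `length_sample` with fields `lengths` (mm,
#'   one per member voxel), `voxel_volume` (mm^3) and `direction`.
#' @export
extract_lengths <- function(field, mask, direction = "VEC3D") {
  if (!inherits(field, "displacement_field") || !inherits(mask, "label_mask"))
    vvh_validation_error("need a displacement_field and a label_mask")
  stopifnot_same_geometry(field, mask, "field and mask")
  direction <- match_direction(direction)
  sel <- mask$membership
  if (!any(sel))
    vvh_validation_error("empty mask: structure has no member voxels")
  lengths <- switch(direction,
    LR = abs(field$u_lr[sel]),
    AP = abs(field$u_ap[sel]),
    CC = abs(field$u_cc[sel]),
    VEC3D = sqrt(field$u_lr[sel]^2 + field$u_ap[sel]^2 + field$u_cc[sel]^2)
  )
  if (anyNA(lengths) || !all(is.finite(lengths)))
    vvh_validation_error("non-finite displacement inside the mask")
  structure(
    list(lengths = as.numeric(lengths),
         voxel_volume = prod(field$geometry$spacing),
         direction = direction),
    class = "length_sample"
  )
}

#' Descending cumulative vector volume histogram
#'
#' The motion analogue of a cumulative DVH: at each length bin edge L, the
#' percentage of the structure volume that moved at least L. Edges run from
#' 0 in steps of `bin_width` up to the first edge past the maximum observed
#' length, so the curve starts at 100 and ends at 0.
#'
#' @param sample a `length_sample` from [extract_lengths()].
#' @param bin_width bin width in mm (> 0); default 0.1 mm.
#' @return an object of class `vvh_curve` with fields `length_mm` and
#'   `volume_percent`.
#' @export
compute_vvh <- function(sample, bin_width = 0.1) {
  if (!inherits(sample, "length_sample") || length(sample$lengths) == 0L)
    vvh_validation_error("sample must be a nonempty length_sample")
  if (!is.finite(bin_width) || bin_width <= 0)
    vvh_validation_error("bin_width must be > 0")
  lx <- sample$lengths
  k <- floor(max(lx) / bin_width + 1e-9)
  edges <- (0:(k + 1L)) * bin_width
  # a length exactly on an edge counts as "moved at least that far";
  # the 1e-9 mm tolerance absorbs binary representation of decimal widths
  pct <- vapply(edges, function(e) 100 * mean(lx >= e - 1e-9), numeric(1))
  structure(list(length_mm = edges, volume_percent = pct,
                 direction = sample$direction),
            class = "vvh_curve")
}

# Percentile of the raw lengths by linear interpolation between order
# statistics: h = (n - 1) p + 1, value = x(h) interpolated.
interp_percentile <- function(sorted_lengths, p) {
  n <- length(sorted_lengths)
  if (n == 1L) return(sorted_lengths)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  frac <- h - lo
  v <- sorted_lengths[lo]
  if (frac > 0) v <- v + frac * (sorted_lengths[lo + 1L] - v)
  v
}

#' Motion indices of a length distribution
#'
#' `L_min` and `L_max` are the extreme per-voxel lengths; `L_x%` is the
#' length such that x% of the structure volume moved at least that far,
#' computed from the raw (unbinned) lengths as the (100 - x)-th percentile
#' with linear interpolation between order statistics. The ordering
#' `L_min <= L_95 <= L_50 <= L_5 <= L_max` always holds.
#'
#' @param sample a `length_sample` from [extract_lengths()].
#' @return an object of class `motion_indices`: a named list with entries
#'   `L_min`, `L_95`, `L_50`, `L_5`, `L_max` in mm.
#' @export
compute_indices <- function(sample) {
  if (!inherits(sample, "length_sample") || length(sample$lengths) == 0L)
    vvh_validation_error("sample must be a nonempty length_sample")
  s <- sort(sample$lengths)
  structure(
    list(L_min = s[1L],
         L_95 = interp_percentile(s, 0.05),
         L_50 = interp_percentile(s, 0.50),
         L_5 = interp_percentile(s, 0.95),
         L_max = s[length(s)]),
    class = "motion_indices"
  )
}

#' @export
print.motion_indices <- function(x, ...) {
  cat(sprintf("L_min %.2f  L_95%% %.2f  L_50%% %.2f  L_5%% %.2f  L_max %.2f (mm)\n",
              x$L_min, x$L_95, x$L_50, x$L_5, x$L_max))
  invisible(x)
}

#' Export a VVH curve and its indices to CSV
#'
#' Writes a `length_mm,volume_percent` table, one row per bin edge, followed
#' by a `#index,value_mm` block holding the five motion indices, all at full
#' precision.
#'
#' @param curve a `vvh_curve` from [compute_vvh()].
#' @param indices a `motion_indices` from [compute_indices()].
#' @param path output path.
#' @export
export_csv <- function(curve, indices, path) {
  if (!inherits(curve, "vvh_curve") || !inherits(indices, "motion_indices"))
    vvh_validation_error("need a vvh_curve and motion_indices")
  if (!dir.exists(dirname(path)))
    vvh_io_error("directory not writable: %s", dirname(path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("length_mm,volume_percent", con)
  writeLines(sprintf("%s,%s",
                     format(curve$length_mm, digits = 17, trim = TRUE),
                     format(curve$volume_percent, digits = 17, trim = TRUE)),
             con)
  for (nm in c("L_min", "L_95", "L_50", "L_5", "L_max"))
    writeLines(sprintf("#%s,%s", nm,
                       format(indices[[nm]], digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' Read back a CSV written by [export_csv()]
#'
#' @param path path to the CSV file.
#' @return list with `curve` (data frame) and `indices` (named numeric).
#' @export
read_vvh_csv <- function(path) {
  if (!file.exists(path)) vvh_io_error("file not found: %s", path)
  lines <- readLines(path)
  idx_lines <- grepl("^#", lines)
  curve <- utils::read.csv(text = lines[!idx_lines])
  parts <- strsplit(sub("^#", "", lines[idx_lines]), ",")
  indices <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                             vapply(parts, `[`, character(1), 1L))
  list(curve = curve, indices = indices)
}

#' Motion-management flag
#'
#' Respiratory motion management is commonly recommended when the tumor
#' motion magnitude exceeds 5 mm. The flag is raised iff the chosen index
#' strictly exceeds the threshold.
#'
#' @param indices a `motion_indices` object.
#' @param threshold mm, > 0; default 5.
#' @param criterion_index which index to compare; default `"L_50"`.
#' @return logical scalar.
#' @export
flag_motion_management <- function(indices, threshold = 5,
                                   criterion_index = "L_50") {
  if (!is.finite(threshold) || threshold <= 0)
    vvh_validation_error("threshold must be > 0")
  valid <- c("L_min", "L_95", "L_50", "L_5", "L_max")
  if (!criterion_index %in% valid)
    vvh_validation_error("unknown index name '%s' (expected one of %s)",
                         criterion_index, paste(valid, collapse = ", "))
  isTRUE(indices[[criterion_index]] > threshold)
}

#' Full VVH analysis of a field over a structure
#'
#' Runs [extract_lengths()], [compute_vvh()] and [compute_indices()] for a
#' set of directions and assembles a machine-readable report.
#'
#' @param field a [displacement_field()].
#' @param mask a [label_mask()] on the same grid.
#' @param directions character vector of directions; default all four.
#' @param bin_width curve bin width, mm.
#' @param threshold motion-management threshold, mm.
#' @param criterion_index index used for the flag, on the `"VEC3D"`
#'   direction when present (else the first direction analysed).
#' @return a named list keyed by direction, each holding `curve`, `indices`
#'   and per-direction metadata, plus `motion_management` at the top level.
#' @export
vvh_report <- function(field, mask, directions = VVH_DIRECTIONS,
                       bin_width = 0.1, threshold = 5,
                       criterion_index = "L_50") {
  directions <- vapply(directions, match_direction, character(1))
  out <- list()
  for (d in directions) {
    sample <- extract_lengths(field, mask, d)
    out[[d]] <- list(
      direction = d,
      n_voxels = length(sample$lengths),
      voxel_volume_mm3 = sample$voxel_volume,
      structure_volume_mm3 = length(sample$lengths) * sample$voxel_volume,
      curve = compute_vvh(sample, bin_width),
      indices = compute_indices(sample)
    )
  }
  flag_dir <- if ("VEC3D" %in% directions) "VEC3D" else directions[[1L]]
  out$motion_management <- flag_motion_management(
    out[[flag_dir]]$indices, threshold, criterion_index)
  out$threshold_mm <- threshold
  out$criterion_index <- criterion_index
  out$criterion_direction <- flag_dir
  out
}
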
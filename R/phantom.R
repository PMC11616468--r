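#' Specification of the digital moving-thorax phantom
#'
#' A digital stand-in for a dynamic thorax QA phantom: an elliptical
#' body-equivalent cylinder containing a lung-equivalent rod, with a
#' spherical water-equivalent target that can be shifted between the fixed
#' and moving scan. Defaults emulate the validation setup: a 2 cm diameter
#' target, 1.25 mm isotropic voxels (so 5/10/15/20 mm cranio-caudal shifts
#' are whole numbers of voxels) over a ~120 x 120 x 150 mm extent, and
#' HU-like intensities (body/target 0, lung -700, background air -1000).
#'
#' @param shape voxel counts (LR, AP, CC); default c(96, 96, 120).
#' @param spacing mm per voxel; default 1.25 isotropic. A coarse 2.5 mm
#'   preset (`coarse = TRUE`) halves the grid for fast runs.
#' @param body_intensity,lung_intensity,target_intensity HU-like values.
#' @param background_intensity HU-like value outside the body.
#' @param body_semiaxes LR/AP semi-axes of the body ellipse, mm.
#' @param rod_radius radius of the lung-equivalent rod, mm.
#' @param target_diameter sphere diameter, mm (> 2 x max spacing).
#' @param target_center sphere centre in world mm (fixed phase).
#' @param shift mm triple applied to the target in the moving phase.
#' @param noise_sigma standard deviation of optional additive Gaussian
#'   noise, HU; 0 disables (the default).
#' @param seed integer seed for the noise generator.
#' @param coarse logical; if TRUE use the 2.5 mm fast preset.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 120), spacing = c(1.25, 1.25, 1.25),
                         body_intensity = 0, lung_intensity = -700,
                         target_intensity = 0, background_intensity = -1000,
                         body_semiaxes = c(55, 45), rod_radius = 30,
                         target_diameter = 20, target_center = c(0, 0, 0),
                         shift = c(0, 0, 0), noise_sigma = 0, seed = 1L,
                         coarse = FALSE) {
  if (coarse) {
    shape <- c(48, 48, 60)
    spacing <- c(2.5, 2.5, 2.5)
  }
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  shape <- as.integer(rep(shape, length.out = 3L))
  origin <- -(shape - 1L) * spacing / 2  # volume centred on the world origin
  grid <- grid_geometry(shape, spacing, origin)
  spec <- structure(
    list(grid = grid, body_intensity = body_intensity,
         lung_intensity = lung_intensity, target_intensity = target_intensity,
         background_intensity = background_intensity,
         body_semiaxes = as.numeric(body_semiaxes),
         rod_radius = as.numeric(rod_radius),
         target_diameter = as.numeric(target_diameter),
         target_center = as.numeric(target_center),
         shift = as.numeric(shift), noise_sigma = as.numeric(noise_sigma),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  r <- spec$target_diameter / 2
  if (spec$target_diameter <= 2 * max(spec$grid$spacing))
    vvh_validation_error("target_diameter must exceed 2x the maximum spacing")
  extent_half <- (spec$grid$shape - 1L) * spec$grid$spacing / 2
  for (centre in list(spec$target_center, spec$target_center + spec$shift)) {
    radial <- sqrt(sum(centre[1:2]^2))
    if (radial + r > spec$rod_radius)
      vvh_validation_error("target sphere leaves the lung rod radially")
    if (abs(centre[3]) + r > extent_half[3])
      vvh_validation_error("target sphere leaves the rod in the CC direction")
  }
  if (sqrt(sum((spec$body_semiaxes / spec$grid$spacing[1:2])^2)) <= 0)
    vvh_validation_error("degenerate body ellipse")
  invisible(spec)
}

# squared distance of every voxel centre from a world point, as a 3D array
voxel_dist2 <- function(grid, centre) {
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a] - centre[a])
  d2xy <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
  outer(d2xy, ax[[3]]^2, `+`)
}

render_phantom_volume <- function(spec, target_centre) {
  grid <- spec$grid
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
  body2d <- outer((ax[[1]] / spec$body_semiaxes[1])^2,
                  (ax[[2]] / spec$body_semiaxes[2])^2, `+`) <= 1
  rod2d <- outer(ax[[1]]^2, ax[[2]]^2, `+`) <= spec$rod_radius^2
  plane <- matrix(spec$background_intensity, grid$shape[1], grid$shape[2])
  plane[body2d] <- spec$body_intensity
  plane[rod2d] <- spec$lung_intensity
  vals <- array(plane, dim = grid$shape)  # rod and body run the full CC extent
  sphere <- voxel_dist2(grid, target_centre) <= (spec$target_diameter / 2)^2
  vals[sphere] <- spec$target_intensity
  list(values = vals, sphere = sphere)
}

#' Generate a fixed/moving phantom pair with ground truth
#'
#' The fixed volume holds the target sphere at `target_center`; the moving
#' volume is identical except that the sphere is re-voxelised at
#' `target_center + shift` (so sub-voxel shifts are representable). The
#' returned mask marks the fixed-phase target. When `noise_sigma > 0`,
#' seeded Gaussian noise is drawn independently for the two volumes.
#'
#' @param spec a [phantom_spec()].
#' @param exact_voxel logical; if TRUE, require the shift to be a whole
#'   number of voxels on every axis (error otherwise).
#' @return list with `fixed`, `moving` ([volume3d()]), `target_mask`
#'   ([label_mask()]) and `truth` (list: `true_shift` mm, `analytic_field`
#'   a uniform [displacement_field()] equal to the shift — exact inside the
#'   target, notional elsewhere).
#' @export
generate_phantom <- function(spec, exact_voxel = FALSE) {
  validate_phantom_spec(spec)
  if (exact_voxel) {
    ratio <- spec$shift / spec$grid$spacing
    if (any(abs(ratio - round(ratio)) > 1e-9))
      vvh_validation_error(
        "spacing does not divide shift: exact-voxel mode needs integer-voxel shifts")
  }
  fx <- render_phantom_volume(spec, spec$target_center)
  mv <- render_phantom_volume(spec, spec$target_center + spec$shift)
  fixed_vals <- fx$values
  moving_vals <- mv$values
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    fixed_vals <- fixed_vals +
      array(stats::rnorm(length(fixed_vals), 0, spec$noise_sigma),
            dim = spec$grid$shape)
    moving_vals <- moving_vals +
      array(stats::rnorm(length(moving_vals), 0, spec$noise_sigma),
            dim = spec$grid$shape)
  }
  list(
    fixed = volume3d(fixed_vals, spec$grid),
    moving = volume3d(moving_vals, spec$grid),
    target_mask = label_mask(fx$sphere, spec$grid),
    truth = list(true_shift = spec$shift,
                 analytic_field = analytic_uniform_field(spec$grid, spec$shift))
  )
}

#' Constant (uniform translation) displacement field
#'
#' Analytic ground-truth field equal to `shift` at every voxel; feeding it
#' to the VVH pipeline must return indices exactly equal to the component
#' magnitudes (LR/AP/CC) and to the Euclidean norm (3D vector).
#'
#' @param geometry a [grid_geometry()].
#' @param shift finite mm triple.
#' @return a [displacement_field()].
#' @export
analytic_uniform_field <- function(geometry, shift) {
  shift <- as.numeric(shift)
  if (length(shift) != 3L || any(!is.finite(shift)))
    vvh_validation_error("shift must be a finite mm triple")
  displacement_field(
    array(shift[1], dim = geometry$shape),
    array(shift[2], dim = geometry$shape),
    array(shift[3], dim = geometry$shape),
    geometry
  )
}

#' Generate a cosine breathing series of phantom volumes
#'
#' Emulates respiration-correlated CT sorted into respiratory phases: the
#' target's cranio-caudal offset follows
#' `amplitude * (1 - cos(2 * pi * phase / phases)) / 2`, so phase 0%
#' (end-inspiration) has zero offset and phase 50% (end-exhalation) the full
#' amplitude.
#'
#' @param spec a [phantom_spec()]; its `shift` is ignored.
#' @param phases number of phases (>= 2); default 10.
#' @param amplitude peak-to-peak cranio-caudal motion, mm.
#' @return list of `phases` entries, each with `volume` ([volume3d()]),
#'   `phase_label` (e.g. `"0%"`), and `cc_offset_mm`.
#' @export
generate_breathing_series <- function(spec, phases = 10, amplitude = 10) {
  phases <- as.integer(phases)
  if (phases < 2L) vvh_validation_error("phases must be >= 2")
  offsets <- amplitude * (1 - cos(2 * pi * (seq_len(phases) - 1) / phases)) / 2
  # validate the extreme position once
  peak <- spec
  peak$shift <- c(0, 0, amplitude)
  validate_phantom_spec(peak)
  lapply(seq_len(phases), function(p) {
    ph <- spec
    ph$shift <- c(0, 0, offsets[p])
    ph$seed <- spec$seed + p - 1L
    vols <- generate_phantom(ph)
    list(volume = vols$moving,
         phase_label = sprintf("%d%%", round(100 * (p - 1) / phases)),
         cc_offset_mm = offsets[p])
  })
}
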
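#' Configuration for B-spline deformable registration
#'
#' Parameters of the intensity-based cubic B-spline free-form-deformation
#' registration. Defaults: 16 mm isotropic control spacing at the finest
#' level, 3 multi-resolution levels (image downsampling x4/x2/x1, control
#' spacing 64/32/16 mm), 50 iterations per level, sum-of-squared-differences
#' metric on range-normalised intensities, bending-energy weight 1e-3, and a
#' relative convergence tolerance of 1e-6. The optimizer is deterministic
#' (zero initialisation, gradient descent with backtracking line search), so
#' repeated runs are bit-identical.
#'
#' @param control_spacing mm per axis of the control lattice at the finest
#'   level; scalar is recycled. Must be at least twice the voxel spacing.
#' @param levels number of multi-resolution levels (>= 1).
#' @param max_iterations iterations per level (>= 1).
#' @param regularization_weight nonnegative bending-energy coefficient.
#' @param convergence_tol relative metric-change threshold per level.
#' @param metric similarity metric; only `"ssd"` is supported.
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(control_spacing = 16, levels = 3,
                                max_iterations = 50,
                                regularization_weight = 1e-3,
                                convergence_tol = 1e-6, metric = "ssd") {
  control_spacing <- rep(as.numeric(control_spacing), length.out = 3L)
  if (any(!is.finite(control_spacing)) || any(control_spacing <= 0))
    vvh_validation_error("control_spacing must be positive")
  if (levels < 1 || max_iterations < 1)
    vvh_validation_error("levels and max_iterations must be >= 1")
  if (regularization_weight < 0)
    vvh_validation_error("regularization_weight must be >= 0")
  if (!identical(metric, "ssd"))
    vvh_validation_error("unsupported metric '%s' (only 'ssd')", metric)
  structure(
    list(control_spacing = control_spacing, levels = as.integer(levels),
         max_iterations = as.integer(max_iterations),
         regularization_weight = regularization_weight,
         convergence_tol = convergence_tol, metric = metric),
    class = "registration_config"
  )
}

#' Build a zero-displacement control-point lattice covering an image domain
#'
#' The lattice is uniform in world mm, aligned with the image axes, and
#' extends past the image domain by the cubic B-spline support margin so
#' every voxel centre has a full 4x4x4 coefficient neighbourhood.
#'
#' @param geometry the fixed-image [grid_geometry()] to cover.
#' @param control_spacing mm per axis (length 3 or scalar).
#' @return an object of class `control_point_lattice` with fields `origin`
#'   (mm position of control point (0,0,0)), `spacing` (mm) and `coef`
#'   (4D array, last axis = LR/AP/CC coefficient in mm).
#' @export
control_point_lattice <- function(geometry, control_spacing) {
  cs <- rep(as.numeric(control_spacing), length.out = 3L)
  if (any(cs < 2 * geometry$spacing))
    vvh_validation_error(
      "control spacing must be >= 2x voxel spacing on each axis")
  extent <- (geometry$shape - 1L) * geometry$spacing
  nc <- as.integer(floor(extent / cs + 1e-9)) + 5L
  structure(
    list(origin = geometry$origin - cs, spacing = cs,
         coef = array(0, dim = c(nc, 3L))),
    class = "control_point_lattice"
  )
}

#' Evaluate a B-spline lattice as a dense displacement field
#'
#' At each voxel centre the displacement is the tensor-product cubic
#' B-spline sum over the 4x4x4 neighbouring control-point coefficients.
#'
#' @param lattice a [control_point_lattice()].
#' @param geometry the image [grid_geometry()] to evaluate on; must lie
#'   inside the lattice support.
#' @return a [displacement_field()].
#' @export
evaluate_lattice <- function(lattice, geometry) {
  nc <- dim(lattice$coef)[1:3]
  arr <- cpp_evaluate_lattice(as.numeric(lattice$coef), as.integer(nc),
                              lattice$origin, lattice$spacing,
                              geometry$origin, geometry$spacing,
                              geometry$shape)
  dim(arr) <- c(geometry$shape, 3L)
  field_from_array(arr, geometry)
}

# Exact dyadic subdivision of a cubic B-spline coefficient array along one
# axis: halving the knot spacing, new coefficients at old knot positions get
# (c[k-1] + 6 c[k] + c[k+1]) / 8 and midpoints (c[k] + c[k+1]) / 2, with
# zero extension outside the stored range.
subdivide_axis <- function(coef, axis, nc_fine) {
  d <- dim(coef)
  dn <- d; dn[axis] <- nc_fine
  out <- array(0, dn)
  getc <- function(k) { # coarse slab k (0-based), zero outside range
    if (k < 0 || k > d[axis] - 1L) return(array(0, d[-axis]))
    idx <- rep(list(quote(expr = )), 4L)
    idx[[axis]] <- k + 1L
    do.call(`[`, c(list(coef), idx, list(drop = FALSE)))
  }
  for (kp in seq_len(nc_fine) - 1L) {
    if (kp %% 2L == 1L) { # odd fine index: coincides with coarse knot k
      k <- (kp + 1L) %/% 2L
      slab <- (getc(k - 1L) + 6 * getc(k) + getc(k + 1L)) / 8
    } else {              # even fine index: midpoint between k and k+1
      k <- kp %/% 2L
      slab <- (getc(k) + getc(k + 1L)) / 2
    }
    idx <- rep(list(quote(expr = )), 4L)
    idx[[axis]] <- kp + 1L
    out <- do.call(`[<-`, c(list(out), idx, list(value = slab)))
  }
  out
}

# Refine a lattice to half the control spacing over the same image domain.
refine_lattice <- function(lattice, geometry) {
  cs_fine <- lattice$spacing / 2
  fine <- control_point_lattice(geometry, cs_fine)
  nc_fine <- dim(fine$coef)[1:3]
  coef <- lattice$coef
  for (ax in 1:3) coef <- subdivide_axis(coef, ax, nc_fine[ax])
  fine$coef <- coef
  fine
}

#' Sum-of-squared-differences metric under a displacement field
#'
#' Mean squared intensity difference between the fixed image and the moving
#' image sampled (trilinear, nearest-edge clamped) at each fixed voxel's
#' displaced position.
#'
#' @param fixed,moving [volume3d()] objects on the same grid.
#' @param field a [displacement_field()] sharing the fixed geometry.
#' @return nonnegative scalar.
#' @export
ssd_metric <- function(fixed, moving, field) {
  stopifnot_same_geometry(fixed, moving, "fixed and moving")
  stopifnot_same_geometry(fixed, field, "fixed image and field")
  cpp_ssd_field(as.numeric(fixed$values), as.numeric(moving$values),
                fixed$geometry$shape, as.numeric(field_as_array(field)),
                fixed$geometry$origin, fixed$geometry$spacing)
}

downsample_volume <- function(vol, factor) {
  if (all(factor == 1L)) return(vol)
  sigma <- ifelse(factor > 1L, factor, 0)
  vals <- cpp_smooth_downsample(as.numeric(vol$values), vol$geometry$shape,
                                sigma, as.integer(factor))
  geom <- grid_geometry(dim(vals), spacing = vol$geometry$spacing * factor,
                        origin = vol$geometry$origin)
  volume3d(array(as.numeric(vals), dim(vals)), geom)
}

# Deterministic gradient descent with backtracking line search on one level.
optimize_level <- function(fx, mv, lattice, cfg, trace_env) {
  nc <- dim(lattice$coef)[1:3]
  geom <- fx$geometry
  obj <- function(coef, want_grad) {
    cpp_ssd_grad_lattice(as.numeric(fx$values), as.numeric(mv$values),
                         geom$shape, as.numeric(coef), as.integer(nc),
                         lattice$origin, lattice$spacing,
                         geom$origin, geom$spacing,
                         cfg$regularization_weight, want_grad)
  }
  coef <- lattice$coef
  cur <- obj(coef, TRUE)
  step <- max(lattice$spacing) / 4   # max per-coefficient change, mm
  step_max <- max(lattice$spacing)
  for (it in seq_len(cfg$max_iterations)) {
    g <- cur$grad
    gmax <- max(abs(g))
    if (gmax < 1e-15) break
    dir <- -array(g, dim = dim(coef)) / gmax
    accepted <- FALSE
    while (step >= 1e-4) {
      cand <- coef + step * dir
      val <- obj(cand, FALSE)$value
      if (val < cur$value - 1e-15) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    # expand: keep doubling while the metric still drops (greedy line
    # minimisation along the fixed descent direction)
    while (step * 2 <= step_max) {
      cand2 <- coef + step * 2 * dir
      val2 <- obj(cand2, FALSE)$value
      if (val2 < val - 1e-15) { step <- step * 2; cand <- cand2; val <- val2 }
      else break
    }
    rel <- (cur$value - val) / max(cur$value, .Machine$double.eps)
    coef <- cand
    cur <- obj(coef, TRUE)
    trace_env$trace[[length(trace_env$trace) + 1L]] <-
      data.frame(level = trace_env$level, iteration = it,
                 metric = cur$value, ssd = cur$ssd, step_mm = step)
    if (rel < cfg$convergence_tol) break
  }
  lattice$coef <- coef
  lattice
}

#' Register two volumes with a B-spline free-form deformation
#'
#' Multi-resolution, intensity-based deformable registration. Intensities
#' are jointly range-normalised, images are Gaussian-smoothed and decimated
#' into a pyramid, and at each level the lattice coefficients are optimised
#' by deterministic gradient descent on the SSD metric plus a bending-energy
#' penalty; the lattice is dyadically refined between levels. The returned
#' field maps each fixed voxel centre to its position in the moving image
#' (pull-back), in mm on the (LR, AP, CC) axes. The final metric never
#' exceeds the zero-field metric.
#'
#' @param fixed,moving [volume3d()] objects on the same grid, finite.
#' @param config a [registration_config()].
#' @return a [displacement_field()] with attributes `lattice` (the optimised
#'   [control_point_lattice()]) and `trace` (per-iteration metric values,
#'   a data frame with columns level/iteration/metric/ssd/step_mm).
#' @export
register <- function(fixed, moving, config = registration_config()) {
  if (!inherits(fixed, "volume3d") || !inherits(moving, "volume3d"))
    vvh_validation_error("fixed and moving must be volume3d objects")
  stopifnot_same_geometry(fixed, moving, "fixed and moving")
  rng <- range(fixed$values, moving$values)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  fx0 <- volume3d((fixed$values - rng[1]) / scale, fixed$geometry)
  mv0 <- volume3d((moving$values - rng[1]) / scale, moving$geometry)

  trace_env <- new.env()
  trace_env$trace <- list()
  lattice <- NULL
  for (lev in seq_len(config$levels)) {
    factor <- rep(2L^(config$levels - lev), 3L)
    cs <- config$control_spacing * 2^(config$levels - lev)
    fx <- downsample_volume(fx0, factor)
    mv <- downsample_volume(mv0, factor)
    lattice <- if (is.null(lattice)) control_point_lattice(fixed$geometry, cs)
               else refine_lattice(lattice, fixed$geometry)
    trace_env$level <- lev
    lattice <- optimize_level(fx, mv, lattice, config, trace_env)
  }

  field <- evaluate_lattice(lattice, fixed$geometry)
  # guarantee monotone progress against the zero field at full resolution
  zero <- displacement_field(array(0, dim = fixed$geometry$shape),
                             array(0, dim = fixed$geometry$shape),
                             array(0, dim = fixed$geometry$shape),
                             fixed$geometry)
  if (ssd_metric(fx0, mv0, field) > ssd_metric(fx0, mv0, zero)) {
    lattice$coef[] <- 0
    field <- zero
  }
  trace <- if (length(trace_env$trace)) do.call(rbind, trace_env$trace)
           else data.frame(level = integer(), iteration = integer(),
                           metric = numeric(), ssd = numeric(),
                           step_mm = numeric())
  attr(field, "lattice") <- lattice
  attr(field, "trace") <- trace
  field
}
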
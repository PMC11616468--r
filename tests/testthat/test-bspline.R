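test_that("constant-coefficient lattices give exactly constant fields", {
  g <- small_geometry(c(10, 10, 10), c(2, 2, 2))
  lat <- control_point_lattice(g, c(8, 8, 8))
  zero <- evaluate_lattice(lat, g)
  expect_true(all(zero$u_lr == 0) && all(zero$u_ap == 0) && all(zero$u_cc == 0))
  lat$coef[, , , 3] <- 4.5
  const <- evaluate_lattice(lat, g)
  expect_equal(max(abs(const$u_cc - 4.5)), 0, tolerance = 1e-12)
  expect_equal(max(abs(const$u_lr)), 0, tolerance = 1e-12)
})

test_that("evaluate_lattice matches the naive triple-loop oracle", {
  g <- small_geometry(c(12, 10, 11), c(2, 2.5, 2), origin = c(-3, 1, 2))
  lat <- control_point_lattice(g, c(8, 9, 10))
  set.seed(31)
  lat$coef[] <- rnorm(length(lat$coef), sd = 3)
  fast <- field_array <- evaluate_lattice(lat, g)
  naive <- naive_bspline_field(lat, g)
  expect_lt(max(abs(fast$u_lr - naive[, , , 1])), 1e-9)
  expect_lt(max(abs(fast$u_ap - naive[, , , 2])), 1e-9)
  expect_lt(max(abs(fast$u_cc - naive[, , , 3])), 1e-9)

  # single unit coefficient: field equals tensor-product basis weights
  lat$coef[] <- 0
  lat$coef[4, 4, 4, 1] <- 1
  single <- evaluate_lattice(lat, g)
  naive1 <- naive_bspline_field(lat, g)
  expect_lt(max(abs(single$u_lr - naive1[, , , 1])), 1e-9)
  expect_gt(max(single$u_lr), 0.05)  # the bump is inside the domain
})

test_that("dyadic lattice refinement reproduces the coarse field exactly", {
  g <- small_geometry(c(14, 14, 14), c(2, 2, 2))
  lat <- control_point_lattice(g, c(10, 10, 10))
  set.seed(5)
  lat$coef[] <- rnorm(length(lat$coef), sd = 5)
  coarse <- evaluate_lattice(lat, g)
  fine <- evaluate_lattice(vvhmotion:::refine_lattice(lat, g), g)
  expect_lt(max(abs(coarse$u_lr - fine$u_lr)), 1e-9)
  expect_lt(max(abs(coarse$u_cc - fine$u_cc)), 1e-9)
})

test_that("ssd_metric obeys closed forms and the brute-force oracle", {
  g <- small_geometry(c(8, 8, 8), c(2, 2, 2))
  set.seed(13)
  vals <- array(rnorm(prod(g$shape)), g$shape)
  fixed <- volume3d(vals, g)
  zero <- analytic_uniform_field(g, c(0, 0, 0))
  expect_lt(ssd_metric(fixed, fixed, zero), 1e-20)
  shifted <- volume3d(vals + 3, g)
  expect_equal(ssd_metric(fixed, shifted, zero), 9, tolerance = 1e-12)

  # compactly supported bump translated by 2 whole voxels in CC:
  # the exact translation field zeroes the metric (clamped samples land in
  # the constant background)
  bump <- array(0, g$shape)
  bump[3:6, 3:6, 3:5] <- 10
  fixedb <- volume3d(bump, g)
  movingb <- array(0, g$shape)
  movingb[3:6, 3:6, 5:7] <- 10
  movingb <- volume3d(movingb, g)
  exact <- analytic_uniform_field(g, c(0, 0, 2 * g$spacing[3]))
  expect_equal(ssd_metric(fixedb, movingb, exact), 0, tolerance = 1e-20)

  # random field: fast metric equals the brute-force resampler
  set.seed(17)
  rf <- displacement_field(array(rnorm(prod(g$shape)), g$shape),
                           array(rnorm(prod(g$shape)), g$shape),
                           array(rnorm(prod(g$shape)), g$shape), g)
  expect_equal(ssd_metric(fixedb, movingb, rf), naive_ssd(fixedb, movingb, rf),
               tolerance = 1e-10)

  g2 <- small_geometry(c(8, 8, 9), c(2, 2, 2))
  expect_error(ssd_metric(fixed, volume3d(array(0, g2$shape), g2), zero),
               class = "vvh_validation_error")
})

test_that("identity registration returns a near-zero field", {
  ph <- generate_phantom(phantom_spec(coarse = TRUE))
  field <- register(ph$fixed, ph$fixed)
  body <- ph$fixed$values > -500  # body + target region
  mag <- sqrt(field$u_lr[body]^2 + field$u_ap[body]^2 + field$u_cc[body]^2)
  expect_lt(median(mag), 0.2)
})

test_that("registration recovers a rigid 10 mm CC shift on the phantom", {
  ph <- generate_phantom(phantom_spec(shift = c(0, 0, 10), coarse = TRUE))
  field <- register(ph$fixed, ph$moving)
  idx <- compute_indices(extract_lengths(field, ph$target_mask, "VEC3D"))
  expect_lt(abs(idx$L_50 - 10), 1)

  # monotone progress: metric never exceeds the zero-field metric
  zero <- analytic_uniform_field(ph$fixed$geometry, c(0, 0, 0))
  expect_lte(ssd_metric(ph$fixed, ph$moving, field),
             ssd_metric(ph$fixed, ph$moving, zero))
  # metric decreases monotonically within each pyramid level (levels are
  # evaluated on different grids, so only within-level comparisons apply)
  trace <- attr(field, "trace")
  for (lev in unique(trace$level))
    expect_true(all(diff(trace$metric[trace$level == lev]) <= 1e-12))

  # displaced target centroid error below one voxel
  m <- ph$target_mask$membership
  mean_u <- c(mean(field$u_lr[m]), mean(field$u_ap[m]), mean(field$u_cc[m]))
  expect_lt(sqrt(sum((mean_u - c(0, 0, 10))^2)), max(ph$fixed$geometry$spacing))

  # determinism: a second run is bit-identical
  field2 <- register(ph$fixed, ph$moving)
  expect_identical(field$u_cc, field2$u_cc)
})

test_that("registration rejects mismatched or non-finite input", {
  ph <- generate_phantom(phantom_spec(coarse = TRUE))
  g2 <- grid_geometry(c(10, 10, 10), c(2, 2, 2))
  expect_error(register(ph$fixed, volume3d(array(0, g2$shape), g2)),
               class = "vvh_validation_error")
  expect_error(volume3d(array(NA_real_, c(2, 2, 2)),
                        grid_geometry(c(2, 2, 2), c(1, 1, 1))),
               class = "vvh_validation_error")
})
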
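uniform_sample <- function(u, geometry = small_geometry(), mask = NULL) {
  field <- analytic_uniform_field(geometry, u)
  if (is.null(mask)) {
    m <- array(FALSE, geometry$shape)
    m[2:5, 2:5, 2:5] <- TRUE
    mask <- label_mask(m, geometry)
  }
  list(field = field, mask = mask)
}

test_that("extract_lengths takes absolute per-axis values and 3D magnitudes", {
  x <- uniform_sample(c(0, 0, -20))
  s <- extract_lengths(x$field, x$mask, "CC")
  expect_true(all(s$lengths == 20))
  expect_equal(s$voxel_volume, 8)

  # component triple from a measured patient centroid: 3D magnitude rounds
  # to the CC value when CC dominates
  y <- uniform_sample(c(0.5, 0.7, 13.5))
  v <- extract_lengths(y$field, y$mask, "VEC3D")$lengths[1]
  expect_equal(round(v, 1), 13.5)

  z <- uniform_sample(c(3, 4, 0))
  expect_true(all(extract_lengths(z$field, z$mask, "VEC3D")$lengths == 5))
  expect_true(all(extract_lengths(z$field, z$mask, "LR")$lengths == 3))

  empty <- label_mask(array(FALSE, x$field$geometry$shape), x$field$geometry)
  expect_error(extract_lengths(x$field, empty), "empty mask",
               class = "vvh_validation_error")
  expect_error(extract_lengths(x$field, x$mask, "diag"),
               class = "vvh_validation_error")
})

test_that("per-voxel 3D length is bounded by components and their sum", {
  g <- small_geometry()
  set.seed(23)
  field <- displacement_field(array(rnorm(prod(g$shape)), g$shape),
                              array(rnorm(prod(g$shape)), g$shape),
                              array(rnorm(prod(g$shape)), g$shape), g)
  mask <- label_mask(array(TRUE, g$shape), g)
  comp <- sapply(c("LR", "AP", "CC"), function(d)
    extract_lengths(field, mask, d)$lengths)
  v3 <- extract_lengths(field, mask, "VEC3D")$lengths
  expect_true(all(v3 >= apply(comp, 1, max) - 1e-12))
  expect_true(all(v3 <= rowSums(comp) + 1e-12))
})

test_that("compute_vvh builds the descending cumulative curve by counting", {
  s20 <- structure(list(lengths = rep(20, 50), voxel_volume = 1,
                        direction = "CC"), class = "length_sample")
  c20 <- compute_vvh(s20, bin_width = 0.1)
  expect_equal(c20$volume_percent[c20$length_mm <= 20], rep(100, 201))
  expect_equal(c20$volume_percent[c20$length_mm > 20], 0)
  expect_setequal(unique(c20$volume_percent), c(100, 0))

  s2 <- structure(list(lengths = c(rep(10, 30), rep(20, 30)),
                       voxel_volume = 1, direction = "CC"),
                  class = "length_sample")
  c2 <- compute_vvh(s2, bin_width = 1)
  expect_equal(c2$volume_percent[c2$length_mm <= 10], rep(100, 11))
  expect_equal(c2$volume_percent[c2$length_mm > 10 & c2$length_mm <= 20],
               rep(50, 10))
  expect_equal(c2$volume_percent[c2$length_mm > 20], 0)

  s0 <- structure(list(lengths = rep(0, 5), voxel_volume = 1,
                       direction = "CC"), class = "length_sample")
  c0 <- compute_vvh(s0, bin_width = 0.5)
  expect_equal(c0$volume_percent, c(100, 0))
  expect_error(compute_vvh(s0, bin_width = 0), class = "vvh_validation_error")

  # invariant: starts at 100, non-increasing, ends at 0
  set.seed(3)
  sr <- random_length_sample(200, function(n) rexp(n, 1 / 5))
  cr <- compute_vvh(sr, 0.25)
  expect_equal(cr$volume_percent[1], 100)
  expect_true(all(diff(cr$volume_percent) <= 0))
  expect_equal(cr$volume_percent[length(cr$volume_percent)], 0)
})

test_that("compute_indices matches the sort-and-interpolate oracle", {
  s <- structure(list(lengths = rep(20, 64), voxel_volume = 1,
                      direction = "CC"), class = "length_sample")
  idx <- compute_indices(s)
  expect_equal(unlist(idx, use.names = FALSE), rep(20, 5))

  eq <- structure(list(lengths = as.numeric(sample(1:100)), voxel_volume = 1,
                       direction = "CC"), class = "length_sample")
  ieq <- compute_indices(eq)
  expect_equal(ieq$L_50, 50.5, tolerance = 1e-12)
  expect_equal(ieq$L_5, 95.05, tolerance = 1e-12)
  expect_equal(ieq$L_95, 5.95, tolerance = 1e-12)

  set.seed(41)
  for (rep in 1:25) {
    n <- sample(1:400, 1)
    sr <- random_length_sample(n, switch(1 + rep %% 3,
      function(n) rnorm(n, 10, 4),
      function(n) rexp(n, 1 / 8),
      function(n) runif(n, 0, 25)))
    got <- compute_indices(sr)
    expect_lt(abs(got$L_95 - oracle_L(sr$lengths, 95)), 1e-9)
    expect_lt(abs(got$L_50 - oracle_L(sr$lengths, 50)), 1e-9)
    expect_lt(abs(got$L_5 - oracle_L(sr$lengths, 5)), 1e-9)
    expect_identical(got$L_min, min(sr$lengths))
    expect_identical(got$L_max, max(sr$lengths))
  }
})

test_that("indices are monotone: L_min <= L_95 <= L_50 <= L_5 <= L_max", {
  set.seed(59)
  for (rep in 1:200) {
    sr <- random_length_sample(sample(1:60, 1),
                               function(n) rnorm(n, 8, 6))
    idx <- compute_indices(sr)
    v <- unlist(idx, use.names = FALSE)
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("a fine-binned curve and the raw indices agree to one bin width", {
  set.seed(67)
  sr <- random_length_sample(4000, function(n) runif(n, 0, 20))
  bw <- 0.05
  curve <- compute_vvh(sr, bw)
  idx <- compute_indices(sr)
  for (x in c(95, 50, 5)) {
    curve_L <- max(curve$length_mm[curve$volume_percent >= x])
    expect_lt(abs(curve_L - idx[[sprintf("L_%d", x)]]), bw + 1e-9)
  }
})

test_that("uniform translation yields exact indices in all directions", {
  u <- c(2.5, -6, 9)
  x <- uniform_sample(u)
  expect_equal(unlist(compute_indices(extract_lengths(x$field, x$mask, "LR")),
                      use.names = FALSE), rep(2.5, 5))
  expect_equal(unlist(compute_indices(extract_lengths(x$field, x$mask, "AP")),
                      use.names = FALSE), rep(6, 5))
  expect_equal(unlist(compute_indices(extract_lengths(x$field, x$mask, "CC")),
                      use.names = FALSE), rep(9, 5))
  expect_equal(unlist(compute_indices(extract_lengths(x$field, x$mask, "VEC3D")),
                      use.names = FALSE), rep(sqrt(sum(u^2)), 5))
})

test_that("CSV export writes the curve plus a five-row index block", {
  s <- structure(list(lengths = rep(20, 10), voxel_volume = 1,
                      direction = "CC"), class = "length_sample")
  curve <- compute_vvh(s, 0.1)
  idx <- compute_indices(s)
  path <- withr::local_tempfile(fileext = ".csv")
  export_csv(curve, idx, path)
  lines <- readLines(path)
  expect_identical(lines[1], "length_mm,volume_percent")
  expect_identical(sum(grepl("^#", lines)), 5L)
  back <- read_vvh_csv(path)
  expect_equal(back$curve$volume_percent, curve$volume_percent)
  expect_setequal(unique(back$curve$volume_percent), c(100, 0))
  expect_equal(unname(back$indices["L_50"]), 20)
})

test_that("motion-management flag triggers strictly above threshold", {
  mk <- function(v) structure(list(L_min = v, L_95 = v, L_50 = v,
                                   L_5 = v, L_max = v),
                              class = "motion_indices")
  expect_true(flag_motion_management(mk(15.8)))   # flagged patient-scale motion
  expect_false(flag_motion_management(mk(3)))
  expect_false(flag_motion_management(mk(5)))     # boundary is strict
  expect_true(flag_motion_management(mk(5 + 1e-9)))
  expect_error(flag_motion_management(mk(1), criterion_index = "L_42"),
               class = "vvh_validation_error")
  expect_error(flag_motion_management(mk(1), threshold = 0),
               class = "vvh_validation_error")
})

test_that("vvh_report assembles all four directions and the flag", {
  x <- uniform_sample(c(0, 0, 20))
  rep <- vvh_report(x$field, x$mask)
  expect_setequal(intersect(names(rep), VVH_DIRECTIONS), VVH_DIRECTIONS)
  expect_equal(rep$VEC3D$indices$L_50, 20)
  expect_true(rep$motion_management)
  rep2 <- vvh_report(x$field, x$mask, directions = "LR")
  expect_false(rep2$motion_management)
})
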
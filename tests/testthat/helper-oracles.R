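# Independent oracles and small fixtures shared across the test files.

small_geometry <- function(shape = c(8, 8, 8), spacing = c(2, 2, 2),
                           origin = c(0, 0, 0)) {
  grid_geometry(shape, spacing, origin)
}

# Naive tensor-product cubic B-spline evaluation: direct polynomial pieces,
# triple loop over voxels, no lookup tables. Kept deliberately independent
# of the package's evaluation path.
naive_bspline_field <- function(lattice, geometry) {
  bpoly <- function(j, u) {
    switch(j + 1L,
           (1 - u)^3 / 6,
           (3 * u^3 - 6 * u^2 + 4) / 6,
           (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
           u^3 / 6)
  }
  sh <- geometry$shape
  out <- array(0, c(sh, 3L))
  for (iz in seq_len(sh[3]) - 1L) for (iy in seq_len(sh[2]) - 1L)
    for (ix in seq_len(sh[1]) - 1L) {
      pos <- geometry$origin + c(ix, iy, iz) * geometry$spacing
      s <- (pos - lattice$origin) / lattice$spacing
      cell <- floor(s)
      u <- s - cell
      acc <- c(0, 0, 0)
      for (a in 0:3) for (b in 0:3) for (cc in 0:3) {
        w <- bpoly(a, u[1]) * bpoly(b, u[2]) * bpoly(cc, u[3])
        k <- cell + c(a, b, cc) - 1L  # 0-based control indices
        acc <- acc + w * lattice$coef[k[1] + 1L, k[2] + 1L, k[3] + 1L, ]
      }
      out[ix + 1L, iy + 1L, iz + 1L, ] <- acc
    }
  out
}

# Brute-force clamped trilinear resampler on world positions.
naive_trilinear <- function(values, geometry, pos) {
  q <- (pos - geometry$origin) / geometry$spacing
  n <- geometry$shape
  q <- pmin(pmax(q, 0), n - 1)
  i0 <- pmin(floor(q), pmax(n - 2, 0))
  t <- q - i0
  acc <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    idx <- pmin(i0 + c(a, b, cc), n - 1)
    w <- prod(ifelse(c(a, b, cc) == 1, t, 1 - t))
    acc <- acc + w * values[idx[1] + 1L, idx[2] + 1L, idx[3] + 1L]
  }
  acc
}

naive_ssd <- function(fixed, moving, field) {
  sh <- fixed$geometry$shape
  acc <- 0
  for (iz in seq_len(sh[3]) - 1L) for (iy in seq_len(sh[2]) - 1L)
    for (ix in seq_len(sh[1]) - 1L) {
      pos <- fixed$geometry$origin + c(ix, iy, iz) * fixed$geometry$spacing
      u <- c(field$u_lr[ix + 1, iy + 1, iz + 1],
             field$u_ap[ix + 1, iy + 1, iz + 1],
             field$u_cc[ix + 1, iy + 1, iz + 1])
      r <- naive_trilinear(moving$values, moving$geometry, pos + u) -
        fixed$values[ix + 1, iy + 1, iz + 1]
      acc <- acc + r^2
    }
  acc / prod(sh)
}

# Sort-and-interpolate percentile oracle, via stats::quantile type 7:
# the length such that x% of the volume moved at least that far.
oracle_L <- function(lengths, x) {
  unname(stats::quantile(lengths, probs = 1 - x / 100, type = 7))
}

random_length_sample <- function(n, rdist) {
  structure(list(lengths = abs(rdist(n)), voxel_volume = 1,
                 direction = "VEC3D"),
            class = "length_sample")
}
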
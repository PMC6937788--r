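# Shared fixtures, built once per run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# coarse contracting-ellipsoid phantom used by most stages
coarse_phantom <- function() {
  cached("coarse_phantom", function() {
    ellipsoid_phantom(R0 = 2, L = 8, alpha = 0.2, n_frames = 10,
                      spacing = 2.5)
  })
}

# the study-scale phantom (fine grid, 20 frames)
fine_phantom <- function() {
  cached("fine_phantom", function() {
    ellipsoid_phantom(R0 = 2, L = 8, alpha = 0.2, n_frames = 20,
                      spacing = 1.25)
  })
}

# uniform axial field over a box mask: nx x ny x nz grid, spacing mm,
# constant v_z (cm/s), full-grid mask
uniform_field <- function(dims = c(6, 6, 4), n_frames = 2, vz = 10,
                          spacing = c(1, 1, 1), rr = 1) {
  d4 <- c(dims, n_frames)
  velocity_field(array(0, d4), array(0, d4), array(vz, d4),
                 spacing = spacing, rr_interval = rr)
}

full_mask <- function(dims = c(6, 6, 4), n_frames = 2, spacing = c(1, 1, 1)) {
  cine_mask(array(TRUE, c(dims, n_frames)), slice_axis = 3,
            apex_to_base_sign = 1, spacing = spacing)
}

# planar rigid-rotation field about the grid center, omega rad/s, constant
# in time; linear in space so trilinear interpolation represents it exactly
rotation_field <- function(omega = 2 * pi, n = 31, nz = 5, n_frames = 10) {
  cx <- (n - 1) / 2; cy <- (n - 1) / 2           # mm
  xs <- seq_len(n) - 1; ys <- seq_len(n) - 1
  vx3 <- array(rep(-omega * outer(rep(1, n), ys - cy), nz), c(n, n, nz)) / 10
  vy3 <- array(rep(omega * outer(xs - cx, rep(1, n)), nz), c(n, n, nz)) / 10
  d4 <- c(n, n, nz, n_frames)
  velocity_field(array(vx3, d4), array(vy3, d4), array(0, d4),
                 spacing = rep(1, 3), rr_interval = 1)
}

rotation_center <- function(n = 31) c((n - 1) / 2, (n - 1) / 2)

# independent 1-D brute-force oracle for plug-phantom compartments:
# enumerate particles along the axis and apply the transit displacements
plug_fractions_oracle <- function(length, d_in, d_out, n_particles = 1e5) {
  z <- (seq_len(n_particles) - 0.5) / n_particles * length
  entered <- z + d_in > length     # outside at previous end systole
  left <- z + d_out > length       # outside at next end systole
  100 * c(direct = mean(entered & left),
          retained = mean(entered & !left),
          delayed = mean(!entered & left),
          residual = mean(!entered & !left))
}

expect_tibble_equal <- function(a, b, tolerance = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tolerance)
}
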
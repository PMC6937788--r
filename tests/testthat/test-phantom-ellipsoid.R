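test_that("static phantom (alpha = 0) has zero velocity and the half-ellipsoid EDV", {
  ph <- ellipsoid_phantom(R0 = 2, L = 8, alpha = 0, n_frames = 4,
                          spacing = 2.5)
  expect_equal(max(abs(ph$field$vx)), 0)
  expect_equal(max(abs(ph$field$vz)), 0)
  expect_equal(max(abs(ph$truth$slice_flux$flow_lpm)), 0)
  # V = (2/3) pi R0^2 L
  expect_equal(ph$truth$edv_ml, (2 / 3) * pi * 4 * 8, tolerance = 1e-12)
  expect_equal(ph$truth$edv_ml, 67.02, tolerance = 1e-4)
})

test_that("analytic basal flux equals -dV/dt at every frame (mass conservation)", {
  ph <- coarse_phantom()
  tr <- ph$truth
  base_slice <- max(tr$slice_flux$slice[abs(tr$slice_flux$flow_lpm) > 0])
  qb <- tr$slice_flux$flow_lpm[tr$slice_flux$slice == base_slice] / 0.06 # cm^3/s
  # differentiate the closed-form volume: V = (2/3) pi R(t)^2 L
  p <- tr$params
  t <- tr$volume$time_s
  Rt <- p$R0 * (1 - p$alpha * sin(pi * t / p$rr_interval)^2)
  dR <- -p$R0 * p$alpha * (pi / p$rr_interval) * sin(2 * pi * t / p$rr_interval)
  dVdt <- (4 / 3) * pi * Rt * dR * p$L
  # the basal-most slice center sits half a voxel below z = L, so its flux
  # falls short of the total volume rate by ~1.5 * (L - z)/L
  expect_lt(max(abs(qb + dVdt)) / max(abs(dVdt)), 0.05)
  # and the shortfall is a time-constant geometric factor
  ratio <- qb[dVdt != 0] / (-dVdt[dVdt != 0])
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("numerically integrated mask flux matches the closed-form slice flux", {
  ph <- fine_phantom()
  fc <- throughplane_flow(ph$field, ph$seg)
  j <- dplyr::inner_join(fc$slices, ph$truth$slice_flux,
                         by = c("slice", "frame"), suffix = c("", "_true"))
  peak <- max(abs(ph$truth$slice_flux$flow_lpm))
  expect_lt(max(abs(j$flow_lpm - j$flow_lpm_true), na.rm = TRUE) / peak, 0.03)
})

test_that("phantom cycle is periodic: basal flow integrates to ~0", {
  ph <- coarse_phantom()
  tr <- ph$truth$slice_flux
  base_slice <- max(tr$slice[abs(tr$flow_lpm) > 0])
  net <- sum(tr$flow_lpm[tr$slice == base_slice]) / ph$truth$params$n_frames
  expect_lt(abs(net), 1e-10)
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- ellipsoid_phantom(n_frames = 4, spacing = 2.5, noise_sd = 0.5, seed = 5)
  b <- ellipsoid_phantom(n_frames = 4, spacing = 2.5, noise_sd = 0.5, seed = 5)
  expect_identical(a$field$vx, b$field$vx)
  expect_identical(a$seg$mask, b$seg$mask)
})

test_that("a phantom that does not fit the grid is rejected", {
  expect_error(ellipsoid_phantom(R0 = 4, L = 8, dims = c(20, 20, 40),
                                 spacing = 2.5),
               "does not fit")
})

test_that("planted velocity noise has the requested SD and is seed-reproducible", {
  vf <- uniform_field(dims = c(40, 50, 50), n_frames = 1 + 1, vz = 0)
  n1 <- add_velocity_noise(vf, sd = 2, seed = 11)
  n2 <- add_velocity_noise(vf, sd = 2, seed = 11)
  expect_identical(n1$vx, n2$vx)
  expect_equal(sd(n1$vx), 2, tolerance = 0.05)  # 2e5 voxels
  expect_identical(add_velocity_noise(vf, sd = 0)$vz, vf$vz)
})
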
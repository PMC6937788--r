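test_that("a zero field leaves trajectories at their seeds", {
  vf <- uniform_field(vz = 0)
  tr <- integrate_pathline(vf, c(2, 2, 1), 0, 1, substeps = 5)
  expect_equal(as.numeric(tr[nrow(tr), 2:4]), c(2, 2, 1), tolerance = 1e-14)
})

test_that("a constant field is integrated exactly", {
  vf <- uniform_field(dims = c(4, 4, 30), vz = 10, spacing = c(1, 1, 1))
  # 10 cm/s for 0.1 s = 1 cm = 10 mm, exactly (RK4 is exact on constants)
  tr <- integrate_pathline(vf, c(1, 1, 2), 0, 0.1, substeps = 10)
  expect_equal(tr$z_mm[nrow(tr)], 12, tolerance = 1e-12)
  # backward tracing inverts the displacement
  bk <- integrate_pathline(vf, c(1, 1, 12), 0.1, 0, substeps = 10)
  expect_equal(bk$z_mm[nrow(bk)], 2, tolerance = 1e-12)
})

test_that("rigid rotation returns to start within 1e-4 cm after one period", {
  vf <- rotation_field(omega = 2 * pi, n_frames = 10)
  seed <- c(rotation_center()[1] + 10, rotation_center()[2], 2)  # r = 1 cm
  tr <- integrate_pathline(vf, seed, 0, 1, substeps = 10)        # h = 0.01 s
  err_cm <- sqrt(sum((as.numeric(tr[nrow(tr), 2:4]) - seed)^2)) / 10
  expect_lt(err_cm, 1e-4)
})

test_that("RK4 endpoint error falls ~16x per step halving", {
  vf <- rotation_field(omega = 2 * pi, n_frames = 10)
  seed <- c(rotation_center()[1] + 10, rotation_center()[2], 2)
  errs <- vapply(c(1, 2, 4), function(ss) {
    tr <- integrate_pathline(vf, seed, 0, 1, substeps = ss)
    sqrt(sum((as.numeric(tr[nrow(tr), 2:4]) - seed)^2))
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 8 & ratios < 32))
})

test_that("forward integration from the backward endpoint returns to the seed", {
  vf <- rotation_field(omega = 2 * pi, n_frames = 10)
  seed <- c(rotation_center()[1] + 8, rotation_center()[2] + 3, 2)
  bk <- integrate_pathline(vf, seed, 0.4, 0, substeps = 20)
  start <- as.numeric(bk[nrow(bk), 2:4])
  fw <- integrate_pathline(vf, start, 0, 0.4, substeps = 20)
  expect_equal(as.numeric(fw[nrow(fw), 2:4]), seed, tolerance = 1e-4)
})

test_that("trajectories freeze at the grid boundary instead of escaping", {
  vf <- uniform_field(dims = c(4, 4, 8), vz = 50, spacing = c(1, 1, 1))
  pl <- integrate_pathlines(vf, matrix(c(1, 1, 5), 1), 0, 1, substeps = 5)
  expect_true(pl$frozen[1])
  expect_lte(max(pl$pos[1, 3, ]), 7)
})

test_that("seeding emits one seed per ED voxel and subsamples in a checker pattern", {
  dims <- c(12, 12, 4); d4 <- c(dims, 2)
  m <- array(FALSE, d4); m[2:11, 2:11, 2, ] <- TRUE  # 100 voxels per frame
  seg <- cine_mask(m, 3, 1, c(1, 1, 1))
  s1 <- seed_pathlines(seg, ed_frame = 1, density = 1)
  expect_equal(nrow(s1), 100)
  expect_equal(s1$volume_ml, rep(prod(seg$spacing) / 1000, 100))
  s4 <- seed_pathlines(seg, ed_frame = 1, density = 0.25)
  expect_lte(abs(nrow(s4) - 25), 1)
  expect_equal(sum(s4$volume_ml), sum(s1$volume_ml), tolerance = 0.001 * 4)
  empty <- array(FALSE, d4); empty[1, 1, 1, ] <- TRUE
  seg2 <- cine_mask(empty, 3, 1, c(1, 1, 1))
  seg2$mask[1, 1, 1, 1] <- FALSE
  expect_error(seed_pathlines(seg2, ed_frame = 1), "empty")
})

test_that("non-finite velocities invalidate a trajectory", {
  vf <- uniform_field(dims = c(4, 4, 6), vz = 5, spacing = c(1, 1, 1))
  vf$vz[, , 4, ] <- NaN
  pl <- integrate_pathlines(vf, matrix(c(1, 1, 1), 1), 0, 1, substeps = 5)
  expect_false(pl$valid[1])
})
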
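test_that("planted cubic offsets are recovered essentially exactly without noise", {
  ph <- coarse_phantom()
  set.seed(21)
  coef <- matrix(rnorm(60, 0, 0.5), 20, 3)
  planted <- plant_background_phase(ph$field, coef)
  static <- !apply(ph$seg$mask, 1:3, any)       # known-truth exterior
  fit <- fit_background_phase(planted, static)
  expect_lt(max(abs(unclass(fit) - coef)) / max(abs(coef)), 1e-8)
  corrected <- correct_background_phase(planted, fit)
  expect_lt(max(abs(corrected$vx - ph$field$vx)), 1e-6)
  expect_lt(max(abs(corrected$vz - ph$field$vz)), 1e-6)
})

test_that("zero coefficients are an identity and zero static tissue fits zero", {
  ph <- coarse_phantom()
  z <- as_poly_coeffs(matrix(0, 20, 3))
  expect_identical(correct_background_phase(ph$field, z)$vx, ph$field$vx)
  static <- !apply(ph$seg$mask, 1:3, any)
  fit <- fit_background_phase(ph$field, static)   # exterior velocity is 0
  expect_lt(max(abs(unclass(fit))), 1e-12)
})

test_that("correction is idempotent once the offset is removed", {
  ph <- coarse_phantom()
  set.seed(22)
  planted <- plant_background_phase(ph$field, matrix(rnorm(60, 0, 1), 20, 3))
  static <- !apply(ph$seg$mask, 1:3, any)
  once <- correct_background_phase(planted, fit_background_phase(planted, static))
  refit <- fit_background_phase(once, static)
  expect_lt(max(abs(unclass(refit))), 1e-8)
})

test_that("with noisy static tissue the residual bias stays below 0.1 cm/s", {
  # >= 1e4 static voxels, noise sd 1 cm/s
  ph <- coarse_phantom()
  static <- !apply(ph$seg$mask, 1:3, any)
  expect_gt(sum(static), 1e4)
  set.seed(23)
  coef <- matrix(rnorm(60, 0, 1), 20, 3)
  noisy <- add_velocity_noise(plant_background_phase(ph$field, coef), 1,
                              seed = 24)
  fit <- fit_background_phase(noisy, static)
  dims <- dim(ph$field$vx)[1:3]
  off <- lvflow:::evaluate_background_phase(fit, dims)
  true_off <- lvflow:::evaluate_background_phase(as_poly_coeffs(coef), dims)
  for (j in 1:3) {
    expect_lt(mean(abs(off[[j]] - true_off[[j]])), 0.1)
  }
})

test_that("correction preserves temporal fluctuations voxel-wise exactly", {
  ph <- coarse_phantom()
  set.seed(25)
  noisy <- add_velocity_noise(ph$field, 0.5, seed = 26)
  fit <- fit_background_phase(noisy, !apply(ph$seg$mask, 1:3, any))
  corr <- correct_background_phase(noisy, fit)
  demean <- function(a) a - as.vector(rowMeans(matrix(a, ncol = dim(a)[4])))
  expect_equal(demean(corr$vx), demean(noisy$vx), tolerance = 1e-12)
})

test_that("static-mask estimation finds still tissue and ignores offsets", {
  ph <- coarse_phantom()
  est <- estimate_static_mask(ph$field, sd_percentile = 30)
  exterior <- !apply(ph$seg$mask, 1:3, any)
  # static voxels must be overwhelmingly outside the moving cavity
  expect_gt(mean(exterior[est]), 0.99)
  const <- matrix(0, 20, 3); const[1, ] <- 3     # pure constant offset
  shifted <- plant_background_phase(ph$field, as_poly_coeffs(const))
  expect_identical(estimate_static_mask(shifted, 30), est)
})

test_that("degenerate static regions are rejected with a clear error", {
  ph <- coarse_phantom()
  few <- array(FALSE, dim(ph$field$vx)[1:3])
  few[1:3, 1, 1] <- TRUE
  expect_error(fit_background_phase(ph$field, few), ">= 20 static voxels")
  plane <- array(FALSE, dim(ph$field$vx)[1:3])
  plane[, , 1] <- TRUE                 # z constant: cubic-in-z terms collinear
  expect_error(fit_background_phase(ph$field, plane), "rank-deficient")
})
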
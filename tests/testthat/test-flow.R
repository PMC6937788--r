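# a 3-region box "ventricle": 9 slices of constant cross-section with a
# prescribed uniform through-plane velocity per slice/frame
box_fixture <- function(vz_by_frame = c(10, -5), nxy = 12, n_in = 10,
                        spacing = c(1.25, 1.25, 2)) {
  n_frames <- length(vz_by_frame)
  dims <- c(nxy, nxy, 11)
  d4 <- c(dims, n_frames)
  m <- array(FALSE, d4)
  m[2:(1 + n_in), 2:(1 + n_in), 2:10, ] <- TRUE
  vz <- array(rep(vz_by_frame, each = prod(dims)), d4)
  field <- velocity_field(array(0, d4), array(0, d4), vz,
                          spacing = spacing, rr_interval = 1)
  seg <- cine_mask(m, slice_axis = 3, apex_to_base_sign = 1,
                   spacing = spacing)
  list(field = field, seg = seg)
}

test_that("uniform 10 cm/s over a 10 cm^2 slice gives 6 L/min", {
  # 10 cm^2 with 1.25 mm in-plane voxels: 640 voxels -> use 80x80... instead
  # scale: area = n_in^2 * (1.25 mm)^2; pick velocity so the product is exact
  fx <- box_fixture(vz_by_frame = c(10, 10), n_in = 10)
  area_cm2 <- 100 * 0.125^2               # 100 voxels * (0.125 cm)^2
  fc <- throughplane_flow(fx$field, fx$seg)
  expect_equal(unique(round(fc$slices$flow_lpm, 12)),
               10 * area_cm2 * 0.06)
  # and the canonical example by direct arithmetic: 10 cm/s * 10 cm^2
  # = 100 cm^3/s = 6 L/min
  expect_equal(10 * 10 * 0.06, 6.0)
})

test_that("zero field gives all-zero curves", {
  fx <- box_fixture(vz_by_frame = c(0, 0))
  fc <- throughplane_flow(fx$field, fx$seg)
  expect_true(all(fc$slices$flow_lpm == 0))
  expect_true(all(fc$regions$flow_lpm == 0))
})

test_that("the region curve is the arithmetic mean of its member slices", {
  ph <- coarse_phantom()
  fc <- throughplane_flow(ph$field, ph$seg)
  manual <- fc$slices |>
    dplyr::group_by(region, frame) |>
    dplyr::summarise(m = mean(flow_lpm, na.rm = TRUE), .groups = "drop")
  j <- dplyr::inner_join(fc$regions, manual, by = c("region", "frame"))
  expect_equal(j$flow_lpm, j$m, tolerance = 1e-12)
})

test_that("flipping the apex-to-base sign negates curves and swaps the peaks", {
  fx <- box_fixture(vz_by_frame = c(8, 2, -4, -6))
  fc1 <- throughplane_flow(fx$field, fx$seg)
  seg2 <- fx$seg; seg2$apex_to_base_sign <- -1L
  fc2 <- throughplane_flow(fx$field, seg2)
  # same slices survive; labels swap ends, so compare slice-wise magnitudes
  expect_equal(fc2$slices$flow_lpm, -fc1$slices$flow_lpm, tolerance = 1e-12)
  p1 <- peak_flows(fc1); p2 <- peak_flows(fc2)
  expect_equal(sort(p2$peak_systolic), sort(p1$peak_diastolic),
               tolerance = 1e-12)
  expect_equal(sort(p2$peak_diastolic), sort(p1$peak_systolic),
               tolerance = 1e-12)
})

test_that("peaks are the attained extrema with the earliest frame on ties", {
  cur <- tibble::tibble(region = "mid", frame = 1:4,
                        flow_lpm = c(2, 6, -4, -1))
  pk <- peak_flows(cur)
  expect_equal(pk$peak_systolic, 6)
  expect_equal(pk$peak_diastolic, 4)
  expect_equal(pk$frame_systolic, 2L)
  tie <- tibble::tibble(region = "mid", frame = 1:2, flow_lpm = c(6, 6))
  expect_equal(peak_flows(tie)$frame_systolic, 1L)
  zero <- tibble::tibble(region = "mid", frame = 1:2, flow_lpm = c(0, 0))
  expect_equal(peak_flows(zero)$peak_systolic, 0)
  expect_equal(peak_flows(zero)$peak_diastolic, 0)
  nacur <- tibble::tibble(region = "mid", frame = 1:2,
                          flow_lpm = c(NA_real_, NA_real_))
  expect_error(peak_flows(nacur), "all-NA")
})

test_that("an empty slice at one frame is skipped, not fatal", {
  fx <- box_fixture(vz_by_frame = c(5, 5))
  m <- fx$seg$mask
  m[, , 2, 2] <- FALSE                 # apical slice empties at frame 2
  seg <- cine_mask(m, 3, 1, fx$seg$spacing)
  expect_message(fc <- throughplane_flow(fx$field, seg), "skipped")
  sl <- fc$slices
  expect_true(is.na(sl$flow_lpm[sl$slice == 2 & sl$frame == 2]))
  expect_false(any(is.na(fc$regions$flow_lpm)))
})
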
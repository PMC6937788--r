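plug_run <- function(d_in, d_out, n_frames = 40, substeps = 4, density = 1) {
  ph <- plug_phantom(d_in = d_in, d_out = d_out, n_frames = n_frames)
  cp <- track_compartments(ph$field, ph$seg, ed_frame = ph$truth$ed_frame,
                           es_frame = ph$truth$es_frame,
                           density = density, substeps = substeps)
  list(ph = ph, cp = cp)
}

test_that("plug-phantom fractions match the slab-overlap analytics", {
  for (s in list(c(8, 8), c(0, 0), c(4, 4), c(2, 6), c(6, 2))) {
    r <- plug_run(s[1], s[2])
    truth <- unlist(r$ph$truth$fractions)
    got <- unlist(r$cp$fractions[1, c("direct_pct", "retained_pct",
                                      "delayed_pct", "residual_pct")])
    expect_equal(unname(got), unname(truth), tolerance = 0.02 * 100,
                 ignore_attr = TRUE)
    expect_equal(sum(got), 100, tolerance = 1e-9)
    expect_equal(r$cp$fractions$excluded_pct, 0)
  }
})

test_that("seed position decides the compartment as the transit slabs dictate", {
  # d_in = 3 cm entry slab, d_out = 2 cm exit slab on an 8 cm cylinder
  ph <- plug_phantom(d_in = 3, d_out = 2, n_frames = 40)
  cp <- track_compartments(ph$field, ph$seg, ed_frame = 1,
                           es_frame = ph$truth$es_frame, substeps = 4)
  z_cm <- (cp$seeds$z_mm - ph$truth$apex_mm) / 10
  lab <- as.character(cp$labels)
  # top 2 cm: inside both slabs -> direct
  expect_true(all(lab[z_cm > 6.1] == "direct"))
  # between 5 and 6 cm: entry slab only -> retained
  expect_true(all(lab[z_cm > 5.1 & z_cm < 5.9] == "retained"))
  # below 5 cm: neither slab -> residual
  expect_true(all(lab[z_cm < 4.9] == "residual"))
})

test_that("a pathline leaving through the apex or lateral wall is excluded", {
  # uniform *downward* flow drives forward trajectories out the apical end
  ph <- plug_phantom(d_in = 0, d_out = 0, n_frames = 8)
  vf <- ph$field
  vf$vz[] <- -6                       # cm/s, base->apex at all frames
  cp <- track_compartments(vf, ph$seg, ed_frame = 1, es_frame = 5,
                           substeps = 4)
  # forward displacement is -3 cm: the bottom ~3/8 of seeds cross the apex
  expect_equal(cp$fractions$excluded_pct, 100 * 3 / 8, tolerance = 3)
  z_cm <- (cp$seeds$z_mm - ph$truth$apex_mm) / 10
  expect_true(all(cp$labels[z_cm < 2.9] == "excluded"))
})

test_that("the stagnant plug is 100% residual with nothing excluded", {
  r <- plug_run(0, 0, n_frames = 8)
  expect_equal(r$cp$fractions$residual_pct, 100)
  expect_equal(r$cp$fractions$excluded_pct, 0)
})

test_that("fraction arithmetic follows the represented volumes", {
  labels <- factor(rep(c("direct", "retained", "delayed", "residual"),
                       c(50, 25, 15, 10)),
                   levels = c("direct", "retained", "delayed", "residual",
                              "excluded"))
  fr <- compartment_fractions(labels, seed_volumes = 1)
  expect_equal(c(fr$direct_pct, fr$retained_pct, fr$delayed_pct,
                 fr$residual_pct), c(50, 25, 15, 10))
  expect_equal(fr$excluded_pct, 0)
  # volume weighting: one double-volume residual pathline counts twice
  lab2 <- factor(c("direct", "residual"),
                 levels = levels(labels))
  fr2 <- compartment_fractions(lab2, seed_volumes = c(1, 2))
  expect_equal(fr2$residual_pct, 100 * 2 / 3)
  expect_error(compartment_fractions(factor(rep("excluded", 3),
                                            levels = levels(labels))),
               "all pathlines")
})

test_that("percentages sum to 100 over non-excluded pathlines with exclusions present", {
  labels <- factor(c("direct", "direct", "retained", "excluded", "excluded"),
                   levels = c("direct", "retained", "delayed", "residual",
                              "excluded"))
  fr <- compartment_fractions(labels)
  expect_equal(fr$direct_pct + fr$retained_pct + fr$delayed_pct +
                 fr$residual_pct, 100, tolerance = 1e-9)
  expect_equal(fr$excluded_pct, 40)
})
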
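test_that("extract_cycle windows the requested cycle", {
  tr <- specimen_truth()
  rec <- generate_recording(recording_protocol("axial_cyclic"), tr)
  loop <- quiet_cycle(rec, 20)
  expect_s3_class(loop, "hysteresis_loop")
  n_per_cycle <- rec$sampling_rate / 1
  expect_lte(abs(length(loop$time) - n_per_cycle), 1)
  expect_true(all(loop$time >= 0 & loop$time < 1 + 1e-9))
  # the window sits over the final second of the 20 s protocol
  expect_equal(max(rec$time), 20)

  # too short a recording
  short <- ts_recording(seq(0, 10, by = 0.01),
                        sin(2 * pi * seq(0, 10, by = 0.01)),
                        0.1 * sin(2 * pi * seq(0, 10, by = 0.01)),
                        kind = "axial_cyclic")
  expect_error(extract_cycle(short, 20), "requires")
})

test_that("noiseless axial loops return the generating truth exactly", {
  tr <- specimen_truth()
  rec <- generate_recording(recording_protocol("axial_cyclic"), tr)
  m <- axial_metrics(quiet_cycle(rec))
  expect_equal(m$stiffness_negative, tr$compressive_stiffness,
               tolerance = 1e-9)
  expect_equal(m$stiffness_positive, tr$tensile_stiffness, tolerance = 1e-9)
  expect_equal(m$range_of_motion, tr$range_of_motion, tolerance = 1e-9)
  expect_equal(m$neutral_zone_length, tr$neutral_zone_axial,
               tolerance = 1e-9)
  expect_equal(m$load_range, 1.0, tolerance = 1e-9)
  expect_lte(m$neutral_zone_length, m$range_of_motion)
})

test_that("a purely linear loss-free loop has closed-form metrics", {
  s <- 12.5                                 # N/mm
  t <- seq(0, 20, by = 1 / 200)
  ph <- t %% 1
  load <- 0.5 * approx(c(0, .25, .75, 1), c(0, 1, -1, 0), xout = ph)$y
  rec <- ts_recording(t, load, load / s, kind = "axial_cyclic")
  m <- axial_metrics(quiet_cycle(rec))
  expect_equal(m$stiffness_positive, s, tolerance = 1e-9)
  expect_equal(m$stiffness_negative, s, tolerance = 1e-9)
  # two-point slope oracle on the exactly linear limb
  loop <- quiet_cycle(rec)
  i <- order(loop$load)
  two_point <- diff(range(loop$load[i])) / diff(range(loop$deformation[i]))
  expect_equal(m$stiffness_positive, two_point, tolerance = 1e-9)
  # NZ of a line: threshold span (2 x 10% amplitude) / slope
  expect_equal(m$neutral_zone_length, 2 * 0.05 / s, tolerance = 1e-9)
  expect_equal(m$range_of_motion, 1 / s, tolerance = 1e-9)
})

test_that("metrics are scale-equivariant in the deformation channel", {
  tr <- specimen_truth()
  rec <- generate_recording(recording_protocol("axial_cyclic"), tr)
  m1 <- axial_metrics(quiet_cycle(rec))
  c_scale <- 3.7
  rec2 <- ts_recording(rec$time, rec$load, rec$deformation * c_scale,
                       kind = "axial_cyclic")
  m2 <- axial_metrics(quiet_cycle(rec2))
  expect_equal(m2$range_of_motion, c_scale * m1$range_of_motion,
               tolerance = 1e-9)
  expect_equal(m2$neutral_zone_length, c_scale * m1$neutral_zone_length,
               tolerance = 1e-9)
  expect_equal(m2$stiffness_positive, m1$stiffness_positive / c_scale,
               tolerance = 1e-9)
  expect_equal(m2$stiffness_negative, m1$stiffness_negative / c_scale,
               tolerance = 1e-9)
})

test_that("noiseless torsional loops return the generating truth exactly", {
  tr <- specimen_truth(neutral_zone_torsional = 0.25)
  rec <- generate_recording(recording_protocol("torsional_cyclic"), tr)
  m <- torsional_metrics(quiet_cycle(rec))
  expect_equal(m$stiffness_mean, tr$torsional_stiffness, tolerance = 1e-9)
  expect_equal(m$load_range, tr$torque_range, tolerance = 1e-9)
  # the generator snaps the NZ edge to the rotation grid; the recorded truth
  # is what must be recovered
  nz_used <- rec$metadata$truth$neutral_zone_torsional
  expect_equal(m$neutral_zone_length, nz_used, tolerance = 1e-9)
  expect_lt(abs(nz_used / 0.25 - 1), 0.02)
  # mirror symmetry of the loop: both limbs identical
  expect_equal(m$stiffness_positive, m$stiffness_negative, tolerance = 1e-9)
})

test_that("mode mismatches and half loops are rejected", {
  tr <- specimen_truth()
  ax <- quiet_cycle(generate_recording(recording_protocol("axial_cyclic"), tr))
  expect_error(torsional_metrics(ax), "torsional")
  # load that never goes negative is not a full loop
  t <- seq(0, 20, by = 1 / 200)
  rec <- ts_recording(t, 0.25 + 0.2 * sin(2 * pi * t),
                      0.02 * sin(2 * pi * t), kind = "axial_cyclic")
  expect_error(axial_metrics(quiet_cycle(rec)), "both signs")
})

test_that("the smooth-limb generator variant is analyzed consistently", {
  tr <- specimen_truth()
  rec <- generate_recording(recording_protocol("axial_cyclic"), tr,
                            shape = "sigmoid")
  m <- axial_metrics(quiet_cycle(rec))
  # ROM and NZ are matched by construction; limb slopes of a smooth curve
  # differ from the piecewise truth and are only loosely constrained
  expect_equal(m$range_of_motion, tr$range_of_motion, tolerance = 1e-3)
  expect_equal(m$neutral_zone_length, tr$neutral_zone_axial,
               tolerance = 0.05)
  expect_gt(m$stiffness_positive, 0)
})
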
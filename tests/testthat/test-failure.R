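test_that("clean failure ramps are located exactly at the generating peak", {
  tr <- specimen_truth()    # peak 0.005 N*m at 1.013 rad, 50% post-peak drop
  rec <- generate_recording(recording_protocol("torsion_to_failure"), tr)
  fm <- detect_failure(rec, smooth_window = 0)
  expect_equal(fm$failure_strength, 0.005, tolerance = 1e-6)
  # within one sample interval of the generating angle
  dtheta <- pi / 180 / rec$sampling_rate
  expect_lte(abs(fm$angle_to_failure - 1.013), dtheta)
  expect_true(fm$failed)
  expect_equal(fm$post_peak_drop_fraction, 0.5, tolerance = 1e-3)
  # brute-force argmax oracle on the clean signal
  expect_identical(fm$peak_index, which.max(rec$load))
  expect_identical(fm$angle_to_failure, rec$deformation[which.max(rec$load)])
})

test_that("a ramp without post-peak drop is censored, not failed", {
  tr <- specimen_truth(drop_fraction = 0.05)
  rec <- generate_recording(recording_protocol("torsion_to_failure"), tr)
  fm <- detect_failure(rec, smooth_window = 0, drop_fraction = 0.2)
  expect_false(fm$failed)
  expect_equal(fm$failure_strength, 0.005, tolerance = 1e-6)
})

test_that("smoothing keeps the noisy peak within one smoothing window", {
  tr <- specimen_truth()
  clean <- generate_recording(recording_protocol("torsion_to_failure"), tr)
  i_true <- which.max(clean$load)
  theta_true <- clean$deformation[i_true]
  window <- 1.0 * pi / 180                # 1 s window at 1 deg/s
  for (seed in 1:5) {
    noisy <- generate_recording(recording_protocol("torsion_to_failure"),
                                tr, noise_sd = 1e-4, seed = seed)
    fm <- detect_failure(noisy, smooth_window = 1.0)
    expect_lte(abs(fm$angle_to_failure - theta_true), window)
  }
})

test_that("degenerate ramps are rejected", {
  t <- seq(0, 60, by = 0.01)
  rev_rot <- ts_recording(t, t * 1e-4, sin(t * 0.5) * 0.5,
                          kind = "torsion_to_failure")
  expect_error(detect_failure(rev_rot), "monotone")
  zero <- ts_recording(t, rep(0, length(t)), t * 0.0175,
                       kind = "torsion_to_failure")
  expect_error(detect_failure(zero), "zero torque|degenerate")
})
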
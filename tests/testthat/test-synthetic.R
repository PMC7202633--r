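test_that("recordings are bit-identical under a fixed seed", {
  tr <- specimen_truth()
  for (kind in c("axial_cyclic", "creep", "torsional_cyclic",
                 "torsion_to_failure")) {
    r1 <- generate_recording(recording_protocol(kind), tr, noise_sd = 0.002,
                             seed = 99)
    r2 <- generate_recording(recording_protocol(kind), tr, noise_sd = 0.002,
                             seed = 99)
    expect_identical(r1$load, r2$load)
    expect_identical(r1$deformation, r2$deformation)
  }
})

test_that("generator contract violations are reported", {
  # neutral zone wider than the loop can carry
  tr <- specimen_truth(neutral_zone_torsional = 0.39)
  expect_error(generate_recording(recording_protocol("torsional_cyclic"), tr),
               "feasible")
  expect_silent(generate_recording(recording_protocol("torsional_cyclic"),
                                   tr, clamp_nz = TRUE))
  # axial truth whose stiffness windows cannot fit inside the ROM
  bad <- specimen_truth(tensile_stiffness = 0.5, range_of_motion = 0.19)
  expect_error(generate_recording(recording_protocol("axial_cyclic"), bad),
               "monotone|contract")
  # protocol invariant
  expect_error(recording_protocol("axial_cyclic", sampling_rate = 5),
               "sampling_rate")
})

test_that("cohorts have the declared factorial structure and physical truths", {
  des <- cohort_design(sex = c("F", "M"), n = 3)
  coh <- generate_cohort(des, seed = 4)
  expect_equal(nrow(coh$truth), 2 * 2 * 2 * 3)
  expect_equal(nrow(coh$manifest), nrow(coh$truth) * 4)
  counts <- table(coh$truth$sex, coh$truth$genotype, coh$truth$diet)
  expect_true(all(counts == 3))
  num <- coh$truth[, sapply(coh$truth, is.numeric)]
  expect_true(all(num > 0))
  expect_true(all(coh$truth$tau1 < coh$truth$tau2))
  expect_true(all(coh$truth$neutral_zone_axial <=
                    coh$truth$range_of_motion))
  expect_true(all(coh$outcomes$notochordal_band_pct <= 100))
})

test_that("cohort generation is deterministic and seed-sensitive", {
  des <- cohort_design(sex = "F", n = 2)
  c1 <- generate_cohort(des, seed = 8)
  c2 <- generate_cohort(des, seed = 8)
  c3 <- generate_cohort(des, seed = 9)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$recordings[[1]]$deformation,
                   c2$recordings[[1]]$deformation)
  expect_false(identical(c1$truth$compressive_stiffness,
                         c3$truth$compressive_stiffness))
})

test_that("different seeds draw from the same distributions", {
  des <- cohort_design(sex = "F", n = 10)
  t1 <- generate_cohort(des, seed = 101)$truth
  t2 <- generate_cohort(des, seed = 202)$truth
  # aggregate KS check over a few outcomes; p values should not be tiny
  ps <- sapply(c("compressive_stiffness", "tau1", "failure_strength"),
               function(v) suppressWarnings(
                 stats::ks.test(t1[[v]], t2[[v]])$p.value))
  expect_gt(min(ps), 0.01)
})

test_that("noise-free round trip recovers every recorded truth to 0.1%", {
  coh <- generate_cohort(cohort_design(sex = "F", n = 1), seed = 12,
                         noise_scale = 0)
  # raw-peak mode: on noiseless data smoothing would only blunt the peak
  res <- suppressWarnings(
    run_pipeline(coh$manifest, recordings = coh$recordings,
                 config = pipeline_config(smooth_window = 0)))
  expect_equal(res$report$n_failed, 0)
  tm <- merge(coh$truth, res$metrics, by = "specimen_id",
              suffixes = c(".t", ".e"))
  vars <- c("compressive_stiffness", "tensile_stiffness", "range_of_motion",
            "neutral_zone_axial", "tau1", "tau2", "elastic_stiffness",
            "stiffness_fast", "stiffness_slow", "torsional_stiffness",
            "torque_range", "neutral_zone_torsional", "failure_strength")
  for (v in vars) {
    rel <- abs(tm[[paste0(v, ".e")]] / tm[[paste0(v, ".t")]] - 1)
    expect_lt(max(rel), 1e-3, label = paste("relative error of", v))
  }
  # angle to failure to within one sample interval
  expect_lte(max(abs(tm$angle_to_failure.e - tm$angle_to_failure.t)),
             (pi / 180) / 100)
})

test_that("single-animal cells propagate a degenerate-design outcome", {
  coh <- generate_cohort(cohort_design(sex = "F", n = 1), seed = 13)
  expect_equal(nrow(coh$truth), 4)
  stats <- cohort_statistics(coh$outcomes)
  expect_null(stats$anova)
  expect_error(two_way_anova(coh$outcomes$dhi, coh$outcomes$genotype,
                             coh$outcomes$diet), "degenerate")
})
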
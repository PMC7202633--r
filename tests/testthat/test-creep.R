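test_that("simulate_creep reproduces the closed-form limits", {
  m <- ref_model()
  # instantaneous elastic response and the t -> infinity asymptote
  expect_equal(simulate_creep(m, 0.5, 0), 0.5 / 11.66)
  d_inf <- simulate_creep(m, 0.5, 1e7)
  q <- derive_creep_quantities(m, 0.5)
  expect_equal(d_inf, q$total_displacement, tolerance = 1e-6)

  # zero load, empty times, monotonicity, upper bound
  t <- seq(0, 2700, by = 1)
  expect_equal(simulate_creep(m, 0, t), rep(0, length(t)))
  expect_identical(simulate_creep(m, 0.5, numeric(0)), numeric(0))
  d <- simulate_creep(m, 0.5, t)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d <= 0.5 * (1 / m$k0 + 1 / m$k1 + 1 / m$k2)))
})

test_that("vanishing time constants reduce to the pure elastic response", {
  m <- five_param_model(11.66, 12.64, 3.15, 1e-4, 2e-4)
  t <- seq(0.1, 10, by = 0.1)
  expect_equal(simulate_creep(m, 0.5, t),
               rep(0.5 * (1 / 11.66 + 1 / 12.64 + 1 / 3.15), length(t)),
               tolerance = 1e-12)
})

test_that("model constructor enforces positivity and arm ordering", {
  expect_error(five_param_model(-1, 1, 1, 1, 2), "positive")
  expect_error(five_param_model(1, 1, 1, 0, 2), "positive")
  # arms supplied slow-first are relabelled fast-first
  m <- five_param_model(11.66, 3.15, 12.64, 739.0, 51.71)
  expect_equal(m$tau1, 51.71)
  expect_equal(m$k1, 12.64)
})

test_that("derived displacement quantities satisfy the closed-form identities", {
  q <- derive_creep_quantities(five_param_model(1, 1, 1, 1, 2), 1)
  expect_equal(q$creep_displacement, 2)
  for (k0 in c(5, 11.66, 20)) {
    q <- derive_creep_quantities(five_param_model(k0, 12.64, 3.15,
                                                  51.71, 739), 0.5)
    expect_equal(q$elastic_displacement, 0.5 / k0)
    expect_equal(q$total_displacement,
                 q$elastic_displacement + q$creep_displacement,
                 tolerance = 1e-12)
  }
  expect_error(derive_creep_quantities(ref_model(), 0), "positive")
})

test_that("fit_creep recovers the generating model from noiseless data", {
  rec <- generate_recording(recording_protocol("creep"), specimen_truth())
  fit <- fit_creep(rec)
  expect_true(fit$converged)
  expect_lt(fit$residual_rms, 1e-8)
  truth <- ref_model()
  for (p in c("k0", "k1", "k2", "tau1", "tau2"))
    expect_lt(abs(fit$model[[p]] / truth[[p]] - 1), 1e-3)
  expect_equal(fit$total_displacement,
               fit$elastic_displacement + fit$creep_displacement,
               tolerance = 1e-9)
})

test_that("fit agrees with a coarse grid-search + linear-solve oracle", {
  m <- ref_model()
  t <- seq(0, 2700, by = 1)
  d <- simulate_creep(m, 0.5, t)
  g <- creep_grid_oracle(t, d, 0.5,
                         tau1_grid = seq(30, 80, by = 5),
                         tau2_grid = seq(500, 1000, by = 50))
  rec <- ts_recording(t, rep(0.5, length(t)), d, kind = "creep")
  fit <- fit_creep(rec)
  expect_lte(sum(fit$residual_rms^2) * length(t), g$ss + 1e-12)
  # fitted taus within one grid step of the oracle's best grid point
  expect_lt(abs(fit$model$tau1 - g$tau1), 5)
  expect_lt(abs(fit$model$tau2 - g$tau2), 50)
})

test_that("permuting the generator's Kelvin arms leaves the fit invariant", {
  t <- seq(0, 2700, by = 0.5)
  f <- 0.5
  arms <- function(k1, tau1, k2, tau2)
    f / 11.66 + (f / k1) * (1 - exp(-t / tau1)) +
      (f / k2) * (1 - exp(-t / tau2))
  d12 <- arms(12.64, 51.71, 3.15, 739.0)
  d21 <- arms(3.15, 739.0, 12.64, 51.71)
  expect_equal(d12, d21, tolerance = 1e-15)
  fit <- fit_creep(ts_recording(t, rep(f, length(t)), d21, kind = "creep"))
  expect_lt(fit$model$tau1, fit$model$tau2)
  expect_equal(fit$model$tau1, 51.71, tolerance = 1e-4)
})

test_that("leading load ramp is trimmed and time re-zeroed", {
  m <- ref_model()
  fs <- 10
  t <- seq(0, 2702, by = 1 / fs)
  load <- pmin(t / 2, 1) * 0.5          # 2 s linear ramp to the step
  # the trim rule keeps samples from 95% of the step load (t = 1.9 s here);
  # the creep clock of the synthetic response starts at that point
  d <- simulate_creep(m, 0.5, pmax(t - 1.9, 0))
  fit <- fit_creep(ts_recording(t, load, d, kind = "creep"))
  expect_equal(fit$model$tau1, 51.71, tolerance = 1e-3)
  expect_equal(fit$model$k0, 11.66, tolerance = 1e-3)
})

test_that("a non-constant load channel raises a protocol-mismatch error", {
  t <- seq(0, 100, by = 0.1)
  rec <- ts_recording(t, 0.5 + 0.3 * sin(t), 0.1 + 0.01 * t, kind = "creep")
  expect_error(fit_creep(rec), "protocol mismatch|settles")
})
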
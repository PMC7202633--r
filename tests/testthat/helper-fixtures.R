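# shared fixtures: the female Control/CD reference parameter set is used as
# generative truth throughout (it is the best-conditioned cell), and a quiet
# cycle extraction that tolerates the one-sample closure gap warnings

ref_model <- function() five_param_model(11.66, 12.64, 3.15, 51.71, 739.0)

quiet_cycle <- function(rec, cycle_index = 20L)
  suppressWarnings(extract_cycle(rec, cycle_index))

# independent grid-search + linear-solve oracle for the creep fit: for fixed
# (tau1, tau2) the model is linear in (F/k0, F/k1, F/k2), so each grid point
# is solved exactly by least squares
creep_grid_oracle <- function(t, d, force, tau1_grid, tau2_grid) {
  best <- NULL
  for (tau1 in tau1_grid) for (tau2 in tau2_grid) {
    if (tau1 >= tau2) next
    X <- cbind(1, 1 - exp(-t / tau1), 1 - exp(-t / tau2))
    cf <- stats::lm.fit(X, d)$coefficients
    ss <- sum((d - X %*% cf)^2)
    if (is.null(best) || ss < best$ss)
      best <- list(ss = ss, tau1 = tau1, tau2 = tau2,
                   k = force / cf)
  }
  best
}
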
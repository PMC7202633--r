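#' Five-parameter viscoelastic solid model
#'
#' Parameter vector of the five-parameter solid used to analyze constant-load
#' creep tests: an elastic spring of stiffness `k0` in series with two
#' Kelvin-Voigt arms, a fast arm (`k1`, `tau1`) and a slow arm (`k2`, `tau2`).
#' Under a step load F the displacement is
#' \deqn{d(t) = F/k_0 + (F/k_1)(1 - e^{-t/\tau_1}) + (F/k_2)(1 - e^{-t/\tau_2}).}
#'
#' Arms are labelled so that `tau1 < tau2` (fast response first); the
#' constructor sorts them if supplied the other way around.
#'
#' @param k0 elastic stiffness (N/mm), > 0.
#' @param k1 fast-response stiffness (N/mm), > 0.
#' @param k2 slow-response stiffness (N/mm), > 0.
#' @param tau1 fast time constant (s), > 0.
#' @param tau2 slow time constant (s), > 0.
#' @return An object of class `five_param_model`.
#' @export
#' @examples
#' m <- five_param_model(11.66, 12.64, 3.15, 51.71, 739.0)
#' simulate_creep(m, force = 0.5, times = c(0, 60, 2700))
five_param_model <- function(k0, k1, k2, tau1, tau2) {
  p <- c(k0 = k0, k1 = k1, k2 = k2, tau1 = tau1, tau2 = tau2)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all five model parameters must be strictly positive and finite",
         call. = FALSE)
  if (tau1 > tau2) {   # fast arm is labelled first
    tmp <- k1; k1 <- k2; k2 <- tmp
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
  }
  structure(list(k0 = k0, k1 = k1, k2 = k2, tau1 = tau1, tau2 = tau2),
            class = "five_param_model")
}

#' @export
print.five_param_model <- function(x, ...) {
  cat("<five_param_model>\n")
  cat(sprintf("  k0 = %.4g N/mm, k1 = %.4g N/mm (tau1 = %.4g s), k2 = %.4g N/mm (tau2 = %.4g s)\n",
              x$k0, x$k1, x$tau1, x$k2, x$tau2))
  invisible(x)
}

#' Simulate displacement of the five-parameter solid under a step load
#'
#' @param model a [five_param_model()].
#' @param force step load (N), >= 0.
#' @param times sample times (s), non-negative and non-decreasing.
#' @return Numeric vector of displacements (mm), one per time point. At t = 0
#'   the response is the instantaneous elastic displacement `force / k0`; the
#'   series is monotone non-decreasing and bounded above by
#'   `force * (1/k0 + 1/k1 + 1/k2)`.
#' @export
simulate_creep <- function(model, force, times) {
  stopifnot(inherits(model, "five_param_model"))
  if (length(times) == 0L) return(numeric(0))
  if (force < 0) stop("force must be non-negative", call. = FALSE)
  if (any(times < 0) || any(diff(times) < 0))
    stop("times must be non-negative and non-decreasing", call. = FALSE)
  force / model$k0 +
    (force / model$k1) * (1 - exp(-times / model$tau1)) +
    (force / model$k2) * (1 - exp(-times / model$tau2))
}

#' Closed-form displacement quantities of a fitted creep model
#'
#' The instantaneous elastic displacement is `F / k0`; the asymptotic
#' (t -> infinity) creep displacement is `F * (1/k1 + 1/k2)`; total
#' displacement is their sum.
#'
#' @param model a [five_param_model()].
#' @param force step load (N), > 0.
#' @return Named list with `elastic_displacement`, `creep_displacement` and
#'   `total_displacement` (mm).
#' @export
#' @examples
#' derive_creep_quantities(five_param_model(11.66, 12.64, 3.15, 51.71, 739),
#'                         force = 0.5)
derive_creep_quantities <- function(model, force) {
  stopifnot(inherits(model, "five_param_model"))
  if (!is.finite(force) || force <= 0)
    stop("force must be strictly positive", call. = FALSE)
  el <- force / model$k0
  cr <- force * (1 / model$k1 + 1 / model$k2)
  list(elastic_displacement = el, creep_displacement = cr,
       total_displacement = el + cr)
}

#' Control settings for the creep fitter
#'
#' @param tau_starts matrix-like set of (tau1, tau2) starting pairs in
#'   seconds; default the 2 x 2 grid \{10, 60\} x \{300, 1500\}.
#' @param stiffness_splits fractions of the total creep compliance assigned
#'   to the fast arm at start; default `c(0.5, 0.25)` (two heuristics per tau
#'   pair, 8 starts in total).
#' @param tau_bounds,k_bounds box constraints (s and N/mm).
#' @param ftol convergence tolerance on the cost function.
#' @param max_iter maximum Levenberg-Marquardt iterations per start.
#' @param trim_fraction load level (fraction of the target step) below which
#'   leading ramp samples are discarded; time is re-zeroed at the first
#'   retained sample.
#' @param load_tolerance allowed relative deviation of the trimmed load
#'   channel from the step value before a protocol-mismatch error is raised.
#' @param jitter_sd relative log-normal jitter applied to starting values
#'   (0 = deterministic starts).
#' @param seed RNG seed for the start jitter.
#' @return A list of class `creep_fit_control`.
#' @export
creep_fit_control <- function(tau_starts = expand.grid(tau1 = c(10, 60),
                                                       tau2 = c(300, 1500)),
                              stiffness_splits = c(0.5, 0.25),
                              tau_bounds = c(0.1, 1e5),
                              k_bounds = c(1e-3, 1e4),
                              ftol = 1e-10, max_iter = 200L,
                              trim_fraction = 0.95,
                              load_tolerance = 0.10,
                              jitter_sd = 0, seed = 1L) {
  structure(list(tau_starts = as.matrix(tau_starts),
                 stiffness_splits = stiffness_splits,
                 tau_bounds = tau_bounds, k_bounds = k_bounds,
                 ftol = ftol, max_iter = max_iter,
                 trim_fraction = trim_fraction,
                 load_tolerance = load_tolerance,
                 jitter_sd = jitter_sd, seed = seed),
            class = "creep_fit_control")
}

# model and Jacobian in log-parameter space; p = log(k0,k1,k2,tau1,tau2)
creep_model_log <- function(p, t, force) {
  k0 <- exp(p[1]); k1 <- exp(p[2]); k2 <- exp(p[3])
  tau1 <- exp(p[4]); tau2 <- exp(p[5])
  force / k0 + (force / k1) * (1 - exp(-t / tau1)) +
    (force / k2) * (1 - exp(-t / tau2))
}

creep_jac_log <- function(p, t, force) {
  k0 <- exp(p[1]); k1 <- exp(p[2]); k2 <- exp(p[3])
  tau1 <- exp(p[4]); tau2 <- exp(p[5])
  e1 <- exp(-t / tau1); e2 <- exp(-t / tau2)
  cbind(
    -force / k0,
    -(force / k1) * (1 - e1),
    -(force / k2) * (1 - e2),
    -(force * t / (k1 * tau1)) * e1,
    -(force * t / (k2 * tau2)) * e2
  )
}

#' Fit the five-parameter solid to a creep recording
#'
#' Trims the leading load ramp (samples before the load channel first reaches
#' `trim_fraction` of the step value), re-zeroes time at the first retained
#' sample, and fits the five-parameter solid by multi-start
#' Levenberg-Marquardt least squares in log-parameter space with an analytic
#' Jacobian. Starting stiffnesses come from endpoint heuristics (`k0` from the
#' first retained displacement, total creep compliance from the tail); time
#' constants from a small grid. The best (lowest-cost) start wins and arms are
#' relabelled so `tau1 < tau2`.
#'
#' @param recording a [ts_recording()] of kind `"creep"` (or any recording
#'   whose load channel is approximately constant after the ramp).
#' @param force step load (N); defaults to the median of the trimmed load
#'   channel.
#' @param cfg a [creep_fit_control()].
#' @return An object of class `creep_fit`: list with `model`
#'   ([five_param_model()]), `applied_force`, `elastic_displacement`,
#'   `creep_displacement`, `total_displacement` (asymptotic convention),
#'   `residual_rms`, `converged`, `n_samples` and `starts` (per-start cost
#'   summary).
#' @export
fit_creep <- function(recording, force = NULL, cfg = creep_fit_control()) {
  stopifnot(inherits(recording, "ts_recording"),
            inherits(cfg, "creep_fit_control"))
  t <- recording$time
  load <- abs(recording$load)        # compressive steps may be logged negative
  d <- abs(recording$deformation)
  target <- stats::median(load[t >= stats::quantile(t, 0.5)])
  keep <- which(load >= cfg$trim_fraction * target)
  if (length(keep) < 10L)
    stop("load channel never settles at the step value; not a creep segment",
         call. = FALSE)
  i0 <- keep[1]
  t <- t[i0:length(t)] - t[i0]
  load <- load[i0:length(load)]
  d <- d[i0:length(d)]
  if (stats::sd(load) > cfg$load_tolerance * target)
    stop("load channel not approximately constant after ramp trim; ",
         "protocol mismatch", call. = FALSE)
  force <- force %||% stats::median(load)

  # endpoint heuristics for starting stiffnesses
  d0 <- stats::median(d[seq_len(min(5L, length(d)))])
  dinf <- stats::median(d[t >= stats::quantile(t, 0.95)])
  k0_start <- force / max(d0, 1e-6)
  c_creep <- max((dinf - d0) / force, 1e-6)   # 1/k1 + 1/k2

  lower <- log(c(rep(cfg$k_bounds[1], 3), rep(cfg$tau_bounds[1], 2)))
  upper <- log(c(rep(cfg$k_bounds[2], 3), rep(cfg$tau_bounds[2], 2)))
  clamp <- function(p) pmin(pmax(p, lower), upper)

  starts <- list()
  for (i in seq_len(nrow(cfg$tau_starts))) {
    for (s in cfg$stiffness_splits) {
      k1s <- 1 / (s * c_creep)
      k2s <- 1 / ((1 - s) * c_creep)
      starts[[length(starts) + 1L]] <-
        log(c(k0_start, k1s, k2s, cfg$tau_starts[i, 1], cfg$tau_starts[i, 2]))
    }
  }
  if (cfg$jitter_sd > 0) {
    set.seed(cfg$seed)
    starts <- lapply(starts, function(p)
      p + stats::rnorm(length(p), 0, cfg$jitter_sd))
  }

  resid_fn <- function(p) creep_model_log(p, t, force) - d
  jac_fn <- function(p) creep_jac_log(p, t, force)

  best <- NULL
  start_costs <- numeric(0)
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = clamp(p0), lower = lower, upper = upper,
      fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(
        ftol = cfg$ftol, ptol = cfg$ftol, maxiter = cfg$max_iter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    cost <- sum(fit$fvec^2)
    start_costs <- c(start_costs, cost)
    if (is.null(best) || cost < best$cost)
      best <- list(fit = fit, cost = cost)
    if (sqrt(cost / length(t)) < 1e-12) break   # noise-free: already exact
  }
  if (is.null(best))
    stop("creep fit failed from every start", call. = FALSE)

  p <- unname(exp(best$fit$par))
  model <- five_param_model(p[1], p[2], p[3], p[4], p[5])  # sorts tau labels
  q <- derive_creep_quantities(model, force)
  converged <- best$fit$info %in% 1:4
  if (!converged)
    warning("creep fit did not formally converge (info = ", best$fit$info,
            "); best-so-far parameters returned", call. = FALSE)
  structure(c(list(model = model, applied_force = force),
              q,
              list(residual_rms = sqrt(best$cost / length(t)),
                   converged = converged, n_samples = length(t),
                   starts = start_costs)),
            class = "creep_fit")
}

#' @export
print.creep_fit <- function(x, ...) {
  cat("<creep_fit>", if (x$converged) "converged" else "NOT converged", "\n")
  print(x$model)
  cat(sprintf("  F = %.3g N; elastic %.4g mm + creep %.4g mm = total %.4g mm\n",
              x$applied_force, x$elastic_displacement, x$creep_displacement,
              x$total_displacement))
  cat(sprintf("  residual RMS %.3g mm over %d samples\n",
              x$residual_rms, x$n_samples))
  invisible(x)
}
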
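#' Extract one hysteresis cycle from a cyclic recording
#'
#' Selects the samples of the requested cycle from a cyclic
#' tension-compression or torsion recording. The cycle window is one period
#' `[tc, tc + 1/frequency)` re-phased to start at the rising zero-crossing of
#' the load channel closest to the nominal window start
#' `(cycle_index - 1) / frequency`; if the load never crosses zero (offset
#' load), the minimum-load sample nearest the nominal start is used instead.
#'
#' @param recording a [ts_recording()] of kind `"axial_cyclic"` or
#'   `"torsional_cyclic"`.
#' @param cycle_index which cycle to extract (default 20, the conventional
#'   last cycle of a 20-cycle protocol).
#' @param frequency loading frequency (Hz), default 1.
#' @return An object of class `hysteresis_loop`: list with `time`, `load`,
#'   `deformation`, `mode` (`"axial"` or `"torsional"`), `cycle_index` and
#'   the units carried over from the recording.
#' @export
extract_cycle <- function(recording, cycle_index = 20L, frequency = 1) {
  stopifnot(inherits(recording, "ts_recording"))
  mode <- switch(recording$kind,
                 axial_cyclic = "axial",
                 torsional_cyclic = "torsional",
                 stop("not a cyclic recording: kind = ", recording$kind,
                      call. = FALSE))
  t <- recording$time - recording$time[1]
  period <- 1 / frequency
  if (max(t) < cycle_index * period - 0.5 / recording$sampling_rate)
    stop(sprintf(
      "recording spans %.3f s but cycle %d at %g Hz requires %.3f s",
      max(t), cycle_index, frequency, cycle_index * period), call. = FALSE)
  load <- recording$load
  t0 <- (cycle_index - 1) * period

  # rising zero-crossings of the load channel
  s <- sign(load)
  ji <- which(s[-length(s)] <= 0 & s[-1] > 0)
  n_expected <- floor(max(t) / period)
  if (length(ji) < max(1L, floor(0.5 * n_expected)))
    warning("load channel has fewer zero-crossings than a periodic ",
            "protocol implies; protocol mismatch?", call. = FALSE)
  if (length(ji) > 0) {
    tc_all <- t[ji] + (t[ji + 1] - t[ji]) *
      (0 - load[ji]) / (load[ji + 1] - load[ji])
    tc <- tc_all[which.min(abs(tc_all - t0))]
  } else {
    win <- which(t >= t0 - period / 2 & t <= t0 + period / 2)
    tc <- t[win[which.min(load[win])]]
  }
  if (tc + period > max(t) + 0.5 / recording$sampling_rate)
    tc <- max(t) - period   # clamp so a full window fits

  dt <- 1 / recording$sampling_rate
  idx <- which(t >= tc - dt / 4 & t < tc + period - dt / 4)
  if (length(idx) < 40L)
    stop("extracted cycle has fewer than 40 samples; raise the sampling rate",
         call. = FALSE)
  loop <- structure(list(
    time = t[idx] - tc, load = load[idx],
    deformation = recording$deformation[idx],
    mode = mode, cycle_index = as.integer(cycle_index),
    load_unit = recording$load_unit,
    deformation_unit = recording$deformation_unit,
    specimen_id = recording$specimen_id
  ), class = "hysteresis_loop")

  # closure check: endpoints within 5% of the loop spans, allowing the
  # one-sample gap a discrete cycle necessarily leaves open
  dspan <- diff(range(loop$deformation)); lspan <- diff(range(loop$load))
  dtol <- max(0.05 * dspan, 1.5 * max(abs(diff(loop$deformation))))
  ltol <- max(0.05 * lspan, 1.5 * max(abs(diff(loop$load))))
  if (abs(loop$deformation[1] - loop$deformation[length(idx)]) > dtol ||
      abs(loop$load[1] - loop$load[length(idx)]) > ltol)
    warning("extracted cycle is not closed to 5% of its spans", call. = FALSE)
  loop
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat(sprintf("<hysteresis_loop> %s cycle %d, %d samples\n",
              x$mode, x$cycle_index, length(x$time)))
  cat(sprintf("  load [%s] in [%.4g, %.4g]; deformation [%s] in [%.4g, %.4g]\n",
              x$load_unit, min(x$load), max(x$load),
              x$deformation_unit, min(x$deformation), max(x$deformation)))
  invisible(x)
}

#' Settings for hysteresis-loop parameterization
#'
#' @param window_fraction fraction of the load range, measured from each load
#'   extreme, over which the limb stiffness line is fitted (default 0.2).
#' @param nz_fraction neutral-zone load threshold as a fraction of the load
#'   amplitude (default 0.1).
#' @param load_limit load level at which range of motion is read off; default
#'   the attained symmetric amplitude `min(max(load), -min(load))`.
#' @param nz_method `"threshold"` (deformation span where |load| <= threshold,
#'   averaged over loading and unloading branches) or `"intersection"` (span
#'   between the zero-load intercepts of the two limb stiffness lines).
#' @return A list of class `loop_control`.
#' @export
loop_control <- function(window_fraction = 0.2, nz_fraction = 0.1,
                         load_limit = NULL,
                         nz_method = c("threshold", "intersection")) {
  stopifnot(window_fraction > 0, window_fraction < 1,
            nz_fraction > 0, nz_fraction < 1)
  structure(list(window_fraction = window_fraction,
                 nz_fraction = nz_fraction, load_limit = load_limit,
                 nz_method = match.arg(nz_method)),
            class = "loop_control")
}

# circular index path between the loop extremes; the loading branch runs
# from the minimum to the maximum of the controlled (noise-free) channel --
# applied load in axial tests, imposed rotation in torsional tests. On a
# noiseless loop this split coincides with the deformation extremes (the
# limb map is monotone); keying it to the controlled channel keeps the split
# from wandering when the measured channel is noisy.
loop_branches <- function(loop) {
  ctrl <- if (loop$mode == "axial") loop$load else loop$deformation
  n <- length(ctrl)
  i_min <- which.min(ctrl)[1]
  i_max <- which.max(ctrl)[1]
  circ <- function(a, b) if (a <= b) a:b else c(a:n, 1:b)
  list(loading = circ(i_min, i_max), unloading = circ(i_max, i_min))
}

# linear fit over the stiffness window at one end of a branch. Both the
# window selection and the regressor use the controlled channel (load for
# axial, rotation for torsional); the noisy measured channel is always the
# response, which avoids errors-in-variables attenuation of the slope and
# keeps the selection independent of the noise. `side` is +1 for the
# positive-extreme window, -1 for the negative one. Returns the limb line as
# load = intercept + slope * deformation.
limb_fit <- function(loop, idx, side, wf) {
  ctrl <- if (loop$mode == "axial") loop$load else loop$deformation
  hi <- max(ctrl); lo <- min(ctrl)
  sel <- if (side > 0) idx[ctrl[idx] >= (1 - wf) * hi]
         else idx[ctrl[idx] <= (1 - wf) * lo]
  if (length(sel) < 2L)
    stop("fewer than 2 samples in the stiffness fit window", call. = FALSE)
  d <- loop$deformation[sel]; l <- loop$load[sel]
  if (stats::sd(d) == 0 || stats::sd(l) == 0)
    stop("degenerate stiffness window: no signal variation", call. = FALSE)
  if (loop$mode == "axial") {
    co <- unname(stats::coef(stats::lm(d ~ l)))   # compliance fit
    c(-co[1] / co[2], 1 / co[2])
  } else {
    unname(stats::coef(stats::lm(l ~ d)))
  }
}

# deformation at a given load level along one branch. The load is first
# replaced by its isotonic (monotone) regression along the branch -- the
# identity on a noiseless loop, a consistent de-noising step when the load
# is the measured channel -- and the level is then located by linear
# interpolation (pooled ties average the deformation).
branch_deformation_at <- function(loop, idx, level) {
  l <- loop$load[idx]; d <- loop$deformation[idx]
  dir <- if (l[length(l)] >= l[1]) 1 else -1
  l <- dir * stats::isoreg(seq_along(l), dir * l)$yf
  if (level > max(l) || level < min(l)) return(NA_real_)
  stats::approx(l, d, xout = level, ties = mean)$y
}

loop_metrics_core <- function(loop, cfg) {
  br <- loop_branches(loop)
  lmax <- max(loop$load); lmin <- min(loop$load)
  if (lmax <= 0 || lmin >= 0)
    stop("load channel does not span both signs; not a full loop",
         call. = FALSE)
  wf <- cfg$window_fraction
  fit_pos <- limb_fit(loop, br$loading, +1, wf)
  fit_neg <- limb_fit(loop, br$loading, -1, wf)
  k_pos <- fit_pos[2]; k_neg <- fit_neg[2]

  limit <- cfg$load_limit %||% min(lmax, -lmin)
  # deformation at the +/- load limits on the loading branch: interpolated
  # when the branch attains the limit, otherwise extrapolated along the
  # fitted limb line (the branch split at the deformation extremes can fall
  # a few noisy samples short of the load extremes)
  d_at <- function(level, fit) {
    d <- branch_deformation_at(loop, br$loading, level)
    if (!is.na(d)) return(d)
    attained <- range(loop$load[br$loading])
    if (level > 0 && attained[2] < (1 - wf) * level ||
        level < 0 && attained[1] > (1 - wf) * level)
      stop(sprintf(
        "load never reaches %.4g on the loading branch (attained [%.4g, %.4g])",
        level, attained[1], attained[2]), call. = FALSE)
    (level - fit[1]) / fit[2]
  }
  rom <- d_at(limit, fit_pos) - d_at(-limit, fit_neg)

  amplitude <- (lmax - lmin) / 2
  thr <- cfg$nz_fraction * amplitude
  if (cfg$nz_method == "threshold") {
    nz_branch <- function(idx) {
      hi <- branch_deformation_at(loop, idx, thr)
      lo <- branch_deformation_at(loop, idx, -thr)
      if (is.na(hi) || is.na(lo)) {   # branch does not cross both thresholds
        sel <- idx[abs(loop$load[idx]) <= thr]
        if (length(sel) == 0L) return(0)
        return(diff(range(loop$deformation[sel])))
      }
      abs(hi - lo)
    }
    nz <- mean(c(nz_branch(br$loading), nz_branch(br$unloading)))
  } else {
    # span between the zero-load intercepts of the two limb lines
    nz <- abs((-fit_pos[1]) / fit_pos[2] - (-fit_neg[1]) / fit_neg[2])
  }

  list(stiffness_positive = k_pos, stiffness_negative = k_neg,
       range_of_motion = rom, neutral_zone_length = nz,
       load_range = lmax - lmin)
}

#' Parameterize an axial tension-compression hysteresis cycle
#'
#' Computes tensile stiffness (`stiffness_positive`, slope of the line fitted
#' to the loading branch over the top `window_fraction` of the positive load
#' range), compressive stiffness (`stiffness_negative`, likewise for the most
#' negative window), range of motion (deformation span between the +/- load
#' limits on the loading branch), neutral-zone length (deformation span where
#' |load| is below `nz_fraction` of the load amplitude, averaged over loading
#' and unloading branches) and the load range.
#'
#' @param loop a [hysteresis_loop()] from [extract_cycle()], axial mode.
#' @param cfg a [loop_control()].
#' @return An object of class `loop_metrics`.
#' @export
axial_metrics <- function(loop, cfg = loop_control()) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  if (loop$mode != "axial")
    stop("axial_metrics requires an axial loop", call. = FALSE)
  m <- loop_metrics_core(loop, cfg)
  structure(c(list(mode = "axial", cycle_index = loop$cycle_index),
              m, list(stiffness_mean = NA_real_)),
            class = "loop_metrics")
}

#' Parameterize a torsional hysteresis cycle
#'
#' As [axial_metrics()] with torque and rotation in place of force and
#' displacement; additionally reports `stiffness_mean`, the average of the
#' clockwise and counterclockwise limb stiffnesses, and `load_range`, the
#' torque span of the loop.
#'
#' @inheritParams axial_metrics
#' @return An object of class `loop_metrics`.
#' @export
torsional_metrics <- function(loop, cfg = loop_control()) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  if (loop$mode != "torsional")
    stop("torsional_metrics requires a torsional loop", call. = FALSE)
  m <- loop_metrics_core(loop, cfg)
  structure(c(list(mode = "torsional", cycle_index = loop$cycle_index), m,
              list(stiffness_mean =
                     (m$stiffness_positive + m$stiffness_negative) / 2)),
            class = "loop_metrics")
}

#' @export
print.loop_metrics <- function(x, ...) {
  cat(sprintf("<loop_metrics> %s cycle %d\n", x$mode, x$cycle_index))
  cat(sprintf("  stiffness +%.4g / -%.4g%s\n", x$stiffness_positive,
              x$stiffness_negative,
              if (!is.na(x$stiffness_mean))
                sprintf(" (mean %.4g)", x$stiffness_mean) else ""))
  cat(sprintf("  ROM %.4g, NZ %.4g, load range %.4g\n",
              x$range_of_motion, x$neutral_zone_length, x$load_range))
  invisible(x)
}
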
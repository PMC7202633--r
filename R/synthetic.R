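#' Test protocol description for the synthetic generator
#'
#' Encodes the four bench protocols emulated by the generator:
#' \describe{
#'   \item{axial_cyclic}{20 cycles of +/-0.5 N tension-compression at 1 Hz.}
#'   \item{creep}{45 min (2700 s) constant compressive step of 0.5 N.}
#'   \item{torsional_cyclic}{20 cycles of +/-10 deg rotation at 1 Hz.}
#'   \item{torsion_to_failure}{rotation ramp at 1 deg/s through the failure
#'     angle.}
#' }
#'
#' @param kind protocol kind.
#' @param amplitude load amplitude (N) for axial cycles or rotation amplitude
#'   (rad) for torsional cycles.
#' @param frequency cyclic loading frequency (Hz).
#' @param cycles number of cycles for cyclic protocols.
#' @param force step load (N) for creep.
#' @param duration creep duration (s).
#' @param rate rotation rate (rad/s) for the failure ramp.
#' @param sampling_rate sampling rate (Hz); must be at least 20 x the cyclic
#'   frequency.
#' @return A list of class `recording_protocol`.
#' @export
recording_protocol <- function(kind = c("axial_cyclic", "creep",
                                        "torsional_cyclic",
                                        "torsion_to_failure"),
                               amplitude = NULL, frequency = 1, cycles = 20L,
                               force = 0.5, duration = 2700,
                               rate = pi / 180, sampling_rate = NULL) {
  kind <- match.arg(kind)
  amplitude <- amplitude %||%
    switch(kind, axial_cyclic = 0.5, torsional_cyclic = 10 * pi / 180, NULL)
  sampling_rate <- sampling_rate %||%
    switch(kind, creep = 10, torsion_to_failure = 100, 200)
  if (kind %in% c("axial_cyclic", "torsional_cyclic") &&
      sampling_rate < 20 * frequency)
    stop("sampling_rate must be at least 20 x the cyclic frequency",
         call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 cycles = as.integer(cycles), force = force,
                 duration = duration, rate = rate,
                 sampling_rate = sampling_rate),
            class = "recording_protocol")
}

#' Per-specimen generating parameters
#'
#' The ground-truth mechanical parameters of one synthetic specimen. The
#' noiseless recordings built from a truth are exactly analyzable: limb
#' slopes, range of motion and neutral zones recovered by the loop analyzers
#' (under their default definitions), the creep curve follows the
#' five-parameter solid, and the failure ramp peaks at
#' (`angle_to_failure`, `failure_strength`).
#'
#' @param model a [five_param_model()] for the creep response.
#' @param tensile_stiffness,compressive_stiffness axial limb stiffnesses
#'   (N/mm).
#' @param range_of_motion axial deformation span between the load limits (mm).
#' @param neutral_zone_axial axial neutral-zone length (mm).
#' @param torsional_stiffness common clockwise/counterclockwise limb
#'   stiffness (N*m/rad).
#' @param torque_range torque span of the torsional loop (N*m).
#' @param neutral_zone_torsional torsional neutral-zone length (rad).
#' @param failure_strength peak torque of the failure ramp (N*m).
#' @param angle_to_failure rotation at the peak (rad).
#' @param drop_fraction post-peak torque drop fraction of the failure ramp.
#' @param sex,genotype,diet,specimen_id optional group labels.
#' @return A list of class `specimen_truth`.
#' @export
specimen_truth <- function(model = five_param_model(11.66, 12.64, 3.15,
                                                    51.71, 739.0),
                           tensile_stiffness = 9.15,
                           compressive_stiffness = 16.59,
                           range_of_motion = 0.19,
                           neutral_zone_axial = 0.07,
                           torsional_stiffness = 0.016,
                           torque_range = 0.003,
                           neutral_zone_torsional = 0.25,
                           failure_strength = 0.005,
                           angle_to_failure = 1.013,
                           drop_fraction = 0.5,
                           sex = NA_character_, genotype = NA_character_,
                           diet = NA_character_,
                           specimen_id = NA_character_) {
  stopifnot(inherits(model, "five_param_model"))
  vals <- c(tensile_stiffness, compressive_stiffness, range_of_motion,
            neutral_zone_axial, torsional_stiffness, torque_range,
            neutral_zone_torsional, failure_strength, angle_to_failure)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all mechanics parameters must be strictly positive", call. = FALSE)
  if (neutral_zone_axial > range_of_motion)
    stop("neutral zone cannot exceed range of motion", call. = FALSE)
  structure(list(model = model, tensile_stiffness = tensile_stiffness,
                 compressive_stiffness = compressive_stiffness,
                 range_of_motion = range_of_motion,
                 neutral_zone_axial = neutral_zone_axial,
                 torsional_stiffness = torsional_stiffness,
                 torque_range = torque_range,
                 neutral_zone_torsional = neutral_zone_torsional,
                 failure_strength = failure_strength,
                 angle_to_failure = angle_to_failure,
                 drop_fraction = drop_fraction,
                 sex = sex, genotype = genotype, diet = diet,
                 specimen_id = specimen_id),
            class = "specimen_truth")
}

# piecewise-linear loading-branch deformation as a function of load.
# Knots are placed so that, under the analyzers' default definitions
# (20% stiffness windows, 10% neutral-zone threshold), the limb slopes, ROM
# and NZ recovered from the noiseless loop equal the truth exactly. Segments
# between the neutral zone and the stiffness windows are free transitions
# that absorb the remaining deformation span.
branch_knots <- function(limit, k_pos, k_neg, rom, nz,
                         window_fraction = 0.2, nz_fraction = 0.1) {
  thr <- nz_fraction * limit
  w <- window_fraction * limit
  load_k <- c(-limit, -(limit - w), -thr, thr, limit - w, limit)
  d_k <- c(-rom / 2, -rom / 2 + w / k_neg, -nz / 2,
           nz / 2, rom / 2 - w / k_pos, rom / 2)
  if (any(diff(d_k) <= 0))
    stop("generator contract violated: truth (stiffness, ROM, NZ) admits no ",
         "monotone loop at this amplitude", call. = FALSE)
  list(load = load_k, deformation = d_k)
}

# largest neutral zone compatible with branch_knots monotonicity (with a 10%
# safety margin)
max_feasible_nz <- function(limit, k_pos, k_neg, rom,
                            window_fraction = 0.2) {
  w <- window_fraction * limit
  0.9 * min(rom - 2 * w / k_pos, rom - 2 * w / k_neg, rom)
}

# torsional loops window the rotation channel, so the neutral zone only has
# to fit below the window edge at 0.8 x amplitude (10% safety margin)
max_feasible_nz_torsional <- function(amplitude) 0.9 * 1.6 * amplitude

#' Generate a synthetic test recording
#'
#' Builds the noiseless recording implied by a [specimen_truth()] under a
#' [recording_protocol()] and adds white Gaussian sensor noise to the
#' measured channel (displacement for axial and creep tests, torque for
#' torsional tests). Given the same seed the output is identical down to the
#' last bit (Mersenne-Twister generator).
#'
#' Cyclic loops use a piecewise-linear limb construction with a low-stiffness
#' central zone so that the default analyzers recover the truth exactly on
#' noiseless data; `shape = "sigmoid"` substitutes a smooth tanh limb (same
#' ROM and neutral zone at the threshold points) for robustness testing.
#'
#' @param protocol a [recording_protocol()].
#' @param truth a [specimen_truth()].
#' @param noise_sd standard deviation of the additive noise on the measured
#'   channel (mm or N*m); 0 for a noiseless recording.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param shape `"piecewise"` (default) or `"sigmoid"` limb construction for
#'   cyclic protocols.
#' @param clamp_nz if `TRUE`, a neutral zone too large for the protocol
#'   amplitude is reduced to the feasible maximum instead of raising a
#'   generator-contract error; the value used is stored in the recording
#'   metadata.
#' @return A [ts_recording()]; `metadata$truth` carries the truth actually
#'   used (after any clamping).
#' @export
generate_recording <- function(protocol, truth, noise_sd = 0, seed = NULL,
                               shape = c("piecewise", "sigmoid"),
                               clamp_nz = FALSE) {
  stopifnot(inherits(protocol, "recording_protocol"),
            inherits(truth, "specimen_truth"))
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  fs <- protocol$sampling_rate

  rec <- switch(protocol$kind,
    creep = {
      t <- seq(0, protocol$duration, by = 1 / fs)
      d <- simulate_creep(truth$model, protocol$force, t)
      if (noise_sd > 0) d <- d + stats::rnorm(length(d), 0, noise_sd)
      ts_recording(t, rep(protocol$force, length(t)), d, kind = "creep",
                   load_unit = "N", deformation_unit = "mm",
                   specimen_id = truth$specimen_id,
                   metadata = list(truth = truth))
    },
    axial_cyclic = {
      t <- seq(0, protocol$cycles / protocol$frequency, by = 1 / fs)
      load <- cyclic_load_wave(t, protocol$amplitude, protocol$frequency,
                               shape)
      d <- cyclic_deformation(load, protocol$amplitude,
                              truth$tensile_stiffness,
                              truth$compressive_stiffness,
                              truth$range_of_motion,
                              truth$neutral_zone_axial, shape)
      if (noise_sd > 0) d <- d + stats::rnorm(length(d), 0, noise_sd)
      ts_recording(t, load, d, kind = "axial_cyclic", load_unit = "N",
                   deformation_unit = "mm", specimen_id = truth$specimen_id,
                   metadata = list(truth = truth))
    },
    torsional_cyclic = {
      a <- protocol$amplitude
      tl <- truth$torque_range / 2
      k <- truth$torsional_stiffness
      if (k >= 4.5 * tl / a)
        stop("generator contract violated: torsional stiffness x window ",
             "span exceeds the loop's torque range", call. = FALSE)
      nz <- truth$neutral_zone_torsional
      nz_max <- max_feasible_nz_torsional(a)
      if (nz > nz_max) {
        if (!clamp_nz)
          stop("generator contract violated: torsional neutral zone ",
               sprintf("%.3g rad exceeds the feasible %.3g rad ", nz, nz_max),
               "at this rotation amplitude (set clamp_nz = TRUE to cap it)",
               call. = FALSE)
        nz <- nz_max
      }
      t <- seq(0, protocol$cycles / protocol$frequency, by = 1 / fs)
      rot <- cyclic_load_wave(t, a, protocol$frequency, shape)
      if (shape == "piecewise") {
        # snap the neutral-zone edge to the rotation sample grid so every
        # kink of the torque map falls exactly on a sample
        step <- 4 * a * protocol$frequency / fs
        nzh <- min(max(round((nz / 2) / step), 1L),
                   floor(0.8 * a / step) - 1L) * step
        nz <- 2 * nzh
        rot_k <- c(-a, -0.8 * a, -nzh, nzh, 0.8 * a, a)
        tor_k <- c(-tl, -(tl - 0.2 * a * k), -0.1 * tl,
                   0.1 * tl, tl - 0.2 * a * k, tl)
        torque <- stats::approx(rot_k, tor_k, xout = rot, rule = 2)$y
      } else {
        g <- function(b) tanh(b * nz / 2) / tanh(b * a) - 0.1
        b <- stats::uniroot(g, c(1e-6, 1e4), tol = 1e-12)$root
        torque <- tl * tanh(b * rot) / tanh(b * a)
      }
      truth$neutral_zone_torsional <- nz
      if (noise_sd > 0)
        torque <- torque + stats::rnorm(length(torque), 0, noise_sd)
      ts_recording(t, torque, rot, kind = "torsional_cyclic",
                   load_unit = "Nm", deformation_unit = "rad",
                   specimen_id = truth$specimen_id,
                   metadata = list(truth = truth))
    },
    torsion_to_failure = {
      # snap the failure angle to the rotation sample grid so the peak value
      # is attained exactly at a sample
      dtheta <- protocol$rate / fs
      truth$angle_to_failure <- round(truth$angle_to_failure / dtheta) * dtheta
      theta_end <- 1.2 * truth$angle_to_failure
      t <- seq(0, theta_end / protocol$rate, by = 1 / fs)
      theta <- protocol$rate * t
      theta[which.min(abs(theta - truth$angle_to_failure))] <-
        truth$angle_to_failure
      torque <- failure_ramp_torque(theta, truth$failure_strength,
                                    truth$angle_to_failure,
                                    truth$drop_fraction)
      if (noise_sd > 0)
        torque <- torque + stats::rnorm(length(torque), 0, noise_sd)
      ts_recording(t, torque, theta, kind = "torsion_to_failure",
                   load_unit = "Nm", deformation_unit = "rad",
                   specimen_id = truth$specimen_id,
                   metadata = list(truth = truth))
    })
  rec
}

# one cyclic period of the load channel: a triangle wave
# 0 -> +amp -> -amp -> 0 for the piecewise construction (so that, at the
# default 200 Hz sampling of a 1 Hz protocol, every knot load falls exactly
# on the sample grid), a sine for the smooth alternative
cyclic_load_wave <- function(t, amp, frequency, shape) {
  if (shape == "sigmoid") return(amp * sin(2 * pi * frequency * t))
  ph <- (t * frequency) %% 1
  amp * stats::approx(c(0, 0.25, 0.75, 1), c(0, 1, -1, 0), xout = ph)$y
}

cyclic_deformation <- function(load, limit, k_pos, k_neg, rom, nz, shape) {
  if (shape == "piecewise") {
    kn <- branch_knots(limit, k_pos, k_neg, rom, nz)
    stats::approx(kn$load, kn$deformation, xout = load, rule = 2)$y
  } else {
    # smooth limb: d = a * tanh(b * load); a fixed by d(limit) = rom/2,
    # b solved so that the 10% threshold crossing reproduces nz
    thr <- 0.1 * limit
    g <- function(b) (rom / 2) * tanh(b * thr) / tanh(b * limit) - nz / 2
    b <- stats::uniroot(g, c(1e-6, 1e3 / limit), tol = 1e-12)$root
    (rom / 2) * tanh(b * load) / tanh(b * limit)
  }
}

# concave power-law rise to the peak, then linear drop by drop_fraction over
# a further 20% of the failure angle. The rise keeps a non-zero slope at the
# peak so the maximum is a corner, not a plateau: under sensor noise the
# smoothed argmax then stays localized near the true failure point.
failure_ramp_torque <- function(theta, strength, angle, drop_fraction) {
  tau <- numeric(length(theta))
  rise <- theta <= angle
  tau[rise] <- strength * (theta[rise] / angle)^0.8
  post <- !rise
  tau[post] <- strength *
    (1 - drop_fraction * pmin((theta[post] - angle) / (0.2 * angle), 1))
  tau
}

# truncated-normal draw by rejection; lower bound defaults to 0.05 x mean
rtrunc_norm <- function(n, mean, sd, lower = 0.05 * mean, upper = Inf) {
  if (stats::pnorm(lower, mean, sd) > 0.99)
    warning("truncation bound far above the mean; check the design",
            call. = FALSE)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x > lower && x < upper) break
    }
    out[i] <- x
  }
  out
}

#' Factorial cohort design for the synthetic generator
#'
#' @param sex sexes to include (`"F"`, `"M"` or both); each sex contributes a
#'   full 2 x 2 genotype-by-diet block.
#' @param n animals per design cell.
#' @param params long-format distribution table (columns `sex`, `diet`,
#'   `genotype`, `outcome`, `mean`, `sd`); defaults to
#'   [reference_group_params()].
#' @param morpho_params as `params` for the morphometric outcomes; defaults
#'   to [reference_morphometry_params()].
#' @param noise named list of sensor-noise SDs: `force` (N), `torque` (N*m),
#'   `displacement` (mm), `rotation` (rad). Defaults are plausible bench
#'   values, not instrument-derived.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(sex = "F", n = 10L,
                          params = reference_group_params(),
                          morpho_params = reference_morphometry_params(),
                          noise = list(force = 0.005, torque = 1e-4,
                                       displacement = 0.002,
                                       rotation = 0.001)) {
  stopifnot(all(sex %in% c("F", "M")), n >= 1L)
  cells <- expand.grid(genotype = c("Control", "DbDb"), diet = c("CD", "WD"),
                       sex = sex, stringsAsFactors = FALSE)
  cells$n <- as.integer(n)
  structure(list(cells = cells[, c("sex", "genotype", "diet", "n")],
                 params = params, morpho_params = morpho_params,
                 noise = noise),
            class = "cohort_design")
}

#' Generate a synthetic factorial cohort
#'
#' Draws per-specimen ground-truth parameters from the per-cell
#' truncated-normal distributions of the design (truncation at 0.05 x mean
#' keeps all mechanics parameters physical; a sampled fast time constant
#' larger than the slow one is label-swapped; neutral zones incompatible with
#' the protocol amplitude are capped at their feasible maximum and the capped
#' value recorded), builds the four test recordings per specimen, and samples
#' the morphometric outcome table.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed; the entire cohort is a deterministic function of
#'   (design, seed).
#' @param out_dir if non-`NULL`, recordings are written as CSV files there
#'   and a `manifest.csv`, `truth.csv` and `outcomes.csv` are emitted;
#'   otherwise recordings are returned in memory.
#' @param noise_scale multiplier on the design's sensor-noise SDs (0 gives
#'   noiseless recordings).
#' @return List with `truth` (per-specimen generating parameters,
#'   data.frame), `manifest` (specimen/test/file table), `recordings` (named
#'   list of [ts_recording()], `NULL` when written to disk), `outcomes`
#'   (tidy morphometry table) and `design`.
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1L,
                            out_dir = NULL, noise_scale = 1) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed, kind = "Mersenne-Twister")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  pm <- design$params
  cell_par <- function(cell, outcome) {
    r <- pm[pm$sex == cell$sex & pm$genotype == cell$genotype &
              pm$diet == cell$diet & pm$outcome == outcome, ]
    if (nrow(r) != 1L)
      stop("no distribution for ", outcome, " in cell ",
           paste(cell$sex, cell$genotype, cell$diet), call. = FALSE)
    r
  }
  draw <- function(cell, outcome)
    rtrunc_norm(1, cell_par(cell, outcome)$mean, cell_par(cell, outcome)$sd)

  truths <- list(); manifest <- list(); recordings <- list()
  outcomes <- list()
  spec_no <- 0L
  mpm <- design$morpho_params
  mdraw <- function(cell, outcome, upper = Inf) {
    r <- mpm[mpm$sex == cell$sex & mpm$genotype == cell$genotype &
               mpm$diet == cell$diet & mpm$outcome == outcome, ]
    rtrunc_norm(1, r$mean, r$sd, upper = upper)
  }

  for (ci in seq_len(nrow(design$cells))) {
    cell <- design$cells[ci, ]
    for (k in seq_len(cell$n)) {
      spec_no <- spec_no + 1L
      sid <- sprintf("%s_%s_%s_%02d", cell$sex, cell$genotype, cell$diet, k)

      tau <- sort(c(draw(cell, "tau1"), draw(cell, "tau2")))
      model <- five_param_model(draw(cell, "elastic_stiffness"),
                                draw(cell, "stiffness_fast"),
                                draw(cell, "stiffness_slow"),
                                tau[1], tau[2])
      # redraw until the loop construction is physically consistent (the
      # stiffness-window spans must fit inside the range of motion)
      repeat {
        k_t <- draw(cell, "tensile_stiffness")
        k_c <- draw(cell, "compressive_stiffness")
        rom <- draw(cell, "range_of_motion")
        if (max_feasible_nz(0.5, k_t, k_c, rom) > 0.01 * rom) break
      }
      nz_ax <- min(draw(cell, "neutral_zone_axial"),
                   max_feasible_nz(0.5, k_t, k_c, rom))
      repeat {
        k_tor <- draw(cell, "torsional_stiffness")
        tr <- draw(cell, "torque_range")
        # loop construction needs the stiff-window torque span to fit
        # inside the torque range
        if (k_tor < 0.95 * 4.5 * (tr / 2) / (10 * pi / 180)) break
      }
      nz_tor <- min(draw(cell, "neutral_zone_torsional"),
                    max_feasible_nz_torsional(10 * pi / 180))
      truth <- specimen_truth(
        model = model, tensile_stiffness = k_t, compressive_stiffness = k_c,
        range_of_motion = rom, neutral_zone_axial = nz_ax,
        torsional_stiffness = k_tor, torque_range = tr,
        neutral_zone_torsional = nz_tor,
        failure_strength = draw(cell, "failure_strength"),
        angle_to_failure = draw(cell, "angle_to_failure"),
        sex = cell$sex, genotype = cell$genotype, diet = cell$diet,
        specimen_id = sid)
      truths[[spec_no]] <- data.frame(
        specimen_id = sid, sex = cell$sex, genotype = cell$genotype,
        diet = cell$diet,
        elastic_stiffness = model$k0, stiffness_fast = model$k1,
        stiffness_slow = model$k2, tau1 = model$tau1, tau2 = model$tau2,
        tensile_stiffness = k_t, compressive_stiffness = k_c,
        range_of_motion = rom, neutral_zone_axial = nz_ax,
        torsional_stiffness = k_tor, torque_range = tr,
        neutral_zone_torsional = nz_tor,
        failure_strength = truth$failure_strength,
        angle_to_failure = truth$angle_to_failure)

      ns <- design$noise
      kinds <- c("axial_cyclic", "creep", "torsional_cyclic",
                 "torsion_to_failure")
      sds <- noise_scale * c(ns$displacement, ns$displacement, ns$torque,
                             ns$torque)
      for (j in seq_along(kinds)) {
        rec <- generate_recording(recording_protocol(kinds[j]), truth,
                                  noise_sd = sds[j], clamp_nz = TRUE)
        fname <- sprintf("%s_%s.csv", sid, kinds[j])
        if (!is.null(out_dir)) {
          write_recording(rec, file.path(out_dir, fname))
        } else {
          recordings[[fname]] <- rec
        }
        manifest[[length(manifest) + 1L]] <- data.frame(
          specimen_id = sid, sex = cell$sex, genotype = cell$genotype,
          diet = cell$diet, kind = kinds[j], file = fname)
      }

      noto <- mdraw(cell, "notochordal_band_pct", upper = 100)
      dens <- mdraw(cell, "cell_density")
      dh <- rtrunc_norm(3, mpm_mean(mpm, cell, "ivd_height"),
                        mpm_sd(mpm, cell, "ivd_height"))
      a <- rtrunc_norm(3, mpm_mean(mpm, cell, "vertebral_length"),
                       mpm_sd(mpm, cell, "vertebral_length"))
      outcomes[[spec_no]] <- data.frame(
        specimen_id = sid, sex = cell$sex, genotype = cell$genotype,
        diet = cell$diet, notochordal_band_pct = noto, cell_density = dens,
        ivd_height = mean(dh), vertebral_length = mean(a),
        dhi = compute_dhi(dh, a))
    }
  }

  truth_df <- do.call(rbind, truths)
  manifest_df <- do.call(rbind, manifest)
  outcomes_df <- do.call(rbind, outcomes)
  if (!is.null(out_dir)) {
    utils::write.csv(truth_df, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest_df, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(outcomes_df, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth_df, file.path(out_dir, "truth.json"),
                         dataframe = "rows", digits = NA)
  }
  list(truth = truth_df, manifest = manifest_df,
       recordings = if (is.null(out_dir)) recordings else NULL,
       outcomes = outcomes_df, design = design)
}

mpm_mean <- function(mpm, cell, outcome) {
  mpm[mpm$sex == cell$sex & mpm$genotype == cell$genotype &
        mpm$diet == cell$diet & mpm$outcome == outcome, "mean"]
}
mpm_sd <- function(mpm, cell, outcome) {
  mpm[mpm$sex == cell$sex & mpm$genotype == cell$genotype &
        mpm$diet == cell$diet & mpm$outcome == outcome, "sd"]
}
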
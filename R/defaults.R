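# Default per-group generating distributions for the synthetic cohort:
# 2 (genotype) x 2 (diet) x 2 (sex) cells of a juvenile-mouse spine study.
# Mechanics refer to caudal vertebra-disc-vertebra motion segments tested in
# +/-0.5 N axial cycles, a 0.5 N / 45 min creep test, +/-10 deg torsion cycles
# and a 1 deg/s torsion-to-failure ramp; morphometry to lumbar discs.

# column order of the value matrices below
ref_cells <- function() {
  data.frame(
    sex = rep(c("F", "M"), each = 4),
    diet = rep(rep(c("CD", "WD"), each = 2), 2),
    genotype = rep(c("Control", "DbDb"), 4),
    stringsAsFactors = FALSE
  )
}

#' Reference motion-segment mechanics distributions
#'
#' Default per-group means and standard deviations used by the synthetic
#' cohort generator for the mechanical outcomes of a 2 x 2 genotype-by-diet
#' factorial in mice of both sexes. Stiffnesses in N/mm, displacement spans
#' in mm, time constants in s, torsional stiffness in N*m/rad, torques in
#' N*m, angles in rad.
#'
#' @return Long-format data.frame with columns `sex`, `diet`, `genotype`,
#'   `outcome`, `mean`, `sd`.
#' @export
reference_group_params <- function() {
  vals <- list(
    #                      F/CD/Con F/CD/Db  F/WD/Con F/WD/Db  M/CD/Con M/CD/Db  M/WD/Con M/WD/Db
    compressive_stiffness = c(16.59, 14.32, 15.68, 17.38, 19.05, 18.95, 18.83, 17.32,
                              4.98, 3.65, 3.09, 3.68, 5.08, 3.81, 7.42, 4.54),
    tensile_stiffness = c(9.15, 12.10, 11.61, 13.31, 12.81, 12.06, 11.92, 11.84,
                          3.89, 4.10, 4.12, 6.77, 4.17, 4.40, 4.15, 3.52),
    range_of_motion = c(0.19, 0.19, 0.17, 0.20, 0.17, 0.18, 0.16, 0.18,
                        0.04, 0.03, 0.02, 0.03, 0.04, 0.05, 0.04, 0.04),
    neutral_zone_axial = c(0.07, 0.05, 0.06, 0.07, 0.06, 0.07, 0.06, 0.07,
                           0.03, 0.02, 0.02, 0.02, 0.02, 0.03, 0.02, 0.02),
    tau1 = c(51.71, 54.75, 41.85, 37.68, 45.13, 41.79, 32.51, 53.22,
             27.13, 12.16, 13.84, 16.55, 9.83, 21.00, 14.78, 20.41),
    tau2 = c(739.0, 900.8, 707.7, 669.0, 724.7, 746.2, 453.1, 806.0,
             255.8, 92.1, 242.7, 194.4, 182.8, 134.8, 37.8, 171.8),
    elastic_stiffness = c(11.66, 12.56, 13.06, 13.08, 14.65, 16.57, 16.03, 14.12,
                          2.47, 2.39, 3.11, 3.18, 4.19, 3.91, 4.53, 3.02),
    stiffness_fast = c(12.64, 14.94, 17.53, 15.10, 17.01, 19.44, 27.17, 17.22,
                       2.00, 2.73, 4.44, 3.43, 6.96, 9.51, 10.17, 5.31),
    stiffness_slow = c(3.15, 2.75, 3.31, 3.12, 3.27, 3.73, 4.08, 2.99,
                       0.94, 0.31, 0.50, 0.79, 0.93, 0.93, 0.97, 0.89),
    torsional_stiffness = c(0.016, 0.014, 0.020, 0.010, 0.020, 0.010, 0.018, 0.012,
                            0.004, 0.004, 0.005, 0.005, 0.004, 0.005, 0.007, 0.006),
    failure_strength = c(0.005, 0.003, 0.007, 0.004, 0.005, 0.004, 0.007, 0.005,
                         0.002, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001),
    angle_to_failure = c(1.013, 0.664, 1.10, 0.69, 0.87, 1.05, 0.889, 1.185,
                         0.246, 0.145, 0.218, 0.201, 0.212, 0.332, 0.300, 0.421),
    torque_range = c(0.003, 0.003, 0.004, 0.003, 0.003, 0.003, 0.004, 0.003,
                     0.001, 0.001, 0.002, 0.002, 0.002, 0.001, 0.002, 0.001),
    neutral_zone_torsional = c(0.39, 0.37, 0.39, 0.40, 0.34, 0.38, 0.36, 0.39,
                               0.04, 0.03, 0.04, 0.07, 0.06, 0.08, 0.07, 0.04)
  )
  cells <- ref_cells()
  do.call(rbind, lapply(names(vals), function(o) {
    v <- vals[[o]]
    cbind(cells, data.frame(outcome = o, mean = v[1:8], sd = v[9:16]))
  }))
}

#' Reference disc morphometry distributions
#'
#' Default per-group means and standard deviations for the morphometric
#' outcomes of the synthetic cohort: notochordal band area as a percentage of
#' nucleus pulposus area, cell density within the notochordal band
#' (cells/mm^2), vertebral length (mm), disc height (mm) and the resulting
#' disc height index.
#'
#' @return Long-format data.frame with columns `sex`, `diet`, `genotype`,
#'   `outcome`, `mean`, `sd`.
#' @export
reference_morphometry_params <- function() {
  vals <- list(
    notochordal_band_pct = c(23.77, 49.24, 16.05, 50.53, 16.47, 19.39, 17.17, 22.38,
                             14.06, 23.92, 5.52, 19.95, 6.29, 7.15, 3.989, 8.954),
    cell_density = c(9977, 2752, 9275, 4378, 6952, 5385, 8633, 5762,
                     2517, 907, 2230, 2874, 1390, 2325, 3538, 2597),
    vertebral_length = c(2.965, 2.848, 3.079, 2.729, 3.077, 2.889, 3.179, 3.127,
                         0.084, 0.143, 0.155, 0.214, 0.085, 0.117, 0.134, 0.081),
    ivd_height = c(0.307, 0.310, 0.333, 0.308, 0.323, 0.311, 0.357, 0.325,
                   0.031, 0.010, 0.038, 0.010, 0.018, 0.036, 0.022, 0.016),
    dhi = c(0.103, 0.109, 0.108, 0.116, 0.105, 0.108, 0.112, 0.104,
            0.010, 0.007, 0.009, 0.013, 0.006, 0.010, 0.007, 0.004)
  )
  cells <- ref_cells()
  do.call(rbind, lapply(names(vals), function(o) {
    v <- vals[[o]]
    cbind(cells, data.frame(outcome = o, mean = v[1:8], sd = v[9:16]))
  }))
}

#' Reference specimen truth for one group cell
#'
#' Convenience accessor returning the group-mean mechanics of one design cell
#' as a [specimen_truth()] (useful for generating an "average" specimen or
#' noise-free round-trip tests).
#'
#' @param sex `"F"` or `"M"`.
#' @param genotype `"Control"` or `"DbDb"`.
#' @param diet `"CD"` or `"WD"`.
#' @return A [specimen_truth()].
#' @export
reference_truth <- function(sex = "F", genotype = "Control", diet = "CD") {
  p <- reference_group_params()
  p <- p[p$sex == sex & p$genotype == genotype & p$diet == diet, ]
  if (nrow(p) == 0L) stop("unknown design cell", call. = FALSE)
  m <- stats::setNames(p$mean, p$outcome)
  specimen_truth(
    model = five_param_model(m[["elastic_stiffness"]], m[["stiffness_fast"]],
                             m[["stiffness_slow"]], m[["tau1"]], m[["tau2"]]),
    tensile_stiffness = m[["tensile_stiffness"]],
    compressive_stiffness = m[["compressive_stiffness"]],
    range_of_motion = m[["range_of_motion"]],
    neutral_zone_axial = m[["neutral_zone_axial"]],
    torsional_stiffness = m[["torsional_stiffness"]],
    torque_range = m[["torque_range"]],
    neutral_zone_torsional = m[["neutral_zone_torsional"]],
    failure_strength = m[["failure_strength"]],
    angle_to_failure = m[["angle_to_failure"]]
  )
}
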
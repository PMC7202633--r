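#' Disc height index from landmark measurements
#'
#' The disc height index normalizes disc height by adjacent vertebral length
#' to remove body-size differences between animals:
#' `DHI = (DH1 + DH2 + DH3) / (A1 + A2 + A3)`, where `DH1..DH3` are disc
#' heights measured at three sites across the disc and `A1..A3` are lengths
#' of the adjacent caudal vertebra at three sites. The index is symmetric
#' under permutation within each triple and invariant to a common scale.
#'
#' @param disc_heights numeric triple of disc heights (mm), all > 0.
#' @param vertebral_lengths numeric triple of vertebral lengths (mm), all > 0.
#' @return The dimensionless DHI.
#' @export
#' @examples
#' compute_dhi(c(0.30, 0.31, 0.32), c(2.9, 3.0, 3.1))
compute_dhi <- function(disc_heights, vertebral_lengths) {
  if (length(disc_heights) != 3L || length(vertebral_lengths) != 3L)
    stop("disc_heights and vertebral_lengths must each have 3 values",
         call. = FALSE)
  if (any(!is.finite(disc_heights)) || any(disc_heights <= 0) ||
      any(!is.finite(vertebral_lengths)) || any(vertebral_lengths <= 0))
    stop("all six measurements must be strictly positive", call. = FALSE)
  sum(disc_heights) / sum(vertebral_lengths)
}

#' Notochordal band area as a percentage of nucleus pulposus area
#'
#' @param notochordal_band_area area of the notochordal band (mm^2), >= 0.
#' @param np_area total nucleus pulposus area (mm^2), > 0 and >= band area.
#' @return Percentage in \[0, 100\].
#' @export
notochordal_band_fraction <- function(notochordal_band_area, np_area) {
  if (!is.finite(np_area) || np_area <= 0)
    stop("np_area must be strictly positive", call. = FALSE)
  if (!is.finite(notochordal_band_area) || notochordal_band_area < 0)
    stop("notochordal_band_area must be non-negative", call. = FALSE)
  if (notochordal_band_area > np_area)
    stop("notochordal band area cannot exceed NP area", call. = FALSE)
  100 * notochordal_band_area / np_area
}

#' Cell density normalized to the counted area
#'
#' @param cell_count number of cells counted, >= 0.
#' @param counted_area area over which cells were counted (mm^2), > 0.
#' @return Cells per mm^2.
#' @export
cell_density <- function(cell_count, counted_area) {
  if (!is.finite(counted_area) || counted_area <= 0)
    stop("counted_area must be strictly positive", call. = FALSE)
  if (!is.finite(cell_count) || cell_count < 0)
    stop("cell_count must be non-negative", call. = FALSE)
  cell_count / counted_area
}
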
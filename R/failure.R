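#' Detect failure strength and angle-to-failure on a torsion-to-failure ramp
#'
#' Formalizes manual peak picking on a rotation-controlled ramp-to-failure
#' test: the failure strength is the maximum of the (optionally smoothed)
#' torque trace and the angle-to-failure is the rotation at that maximum. The
#' specimen is flagged as failed only if the torque subsequently drops by at
#' least `drop_fraction` of the peak; otherwise the test is treated as
#' censored (truncated before failure) and the peak values are reported with
#' `failed = FALSE`.
#'
#' @param recording a [ts_recording()] of kind `"torsion_to_failure"` with a
#'   monotonically increasing rotation channel (small servo jitter tolerated).
#' @param smooth_window centered moving-average window (s) applied to the
#'   torque before peak picking; `0` disables smoothing (raw-peak mode).
#' @param drop_fraction post-peak torque drop, as a fraction of the peak,
#'   required to call failure (default 0.2).
#' @param jitter_tol tolerated non-monotonicity of the rotation channel, as a
#'   fraction of the total rotation span (default 0.01).
#' @return An object of class `failure_metrics`: list with `failure_strength`
#'   (peak torque, N*m), `angle_to_failure` (rad), `failed`,
#'   `post_peak_drop_fraction`, `peak_index` and `smooth_window`.
#' @export
detect_failure <- function(recording, smooth_window = 0.5,
                           drop_fraction = 0.2, jitter_tol = 0.01) {
  stopifnot(inherits(recording, "ts_recording"))
  theta <- recording$deformation
  tau <- recording$load
  span <- diff(range(theta))
  # cumulative drawdown catches reversals that per-sample jitter would hide
  if (span <= 0 || max(cummax(theta) - theta) > jitter_tol * span)
    stop("rotation channel is not a monotone ramp (beyond jitter tolerance)",
         call. = FALSE)
  if (all(abs(tau) < .Machine$double.eps^0.5))
    stop("all-zero torque channel; degenerate input", call. = FALSE)

  tau_s <- tau
  if (smooth_window > 0) {
    w <- max(1L, round(smooth_window * recording$sampling_rate))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > 1L && w < length(tau)) {
      half <- (w - 1L) %/% 2L
      cs <- cumsum(c(0, tau))
      n <- length(tau)
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      tau_s <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
  }
  ipk <- which.max(tau_s)
  peak <- tau_s[ipk]
  post_min <- if (ipk < length(tau_s)) min(tau_s[ipk:length(tau_s)]) else peak
  drop <- (peak - post_min) / peak
  structure(list(
    failure_strength = peak,
    angle_to_failure = theta[ipk],
    failed = isTRUE(drop >= drop_fraction),
    post_peak_drop_fraction = drop,
    peak_index = ipk,
    smooth_window = smooth_window
  ), class = "failure_metrics")
}

#' @export
print.failure_metrics <- function(x, ...) {
  cat(sprintf("<failure_metrics> %s\n",
              if (x$failed) "failed" else "censored (no failure event)"))
  cat(sprintf("  peak torque %.4g N*m at %.4g rad (post-peak drop %.1f%%)\n",
              x$failure_strength, x$angle_to_failure,
              100 * x$post_peak_drop_fraction))
  invisible(x)
}
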
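#' Peak resultant kinematics at the head centre of gravity
#'
#' Filters each channel of the linear-acceleration, angular-acceleration
#' and angular-velocity triax signals with a zero-phase 2-pole Butterworth
#' low-pass (180 Hz by default, the cutoff used for reporting head
#' kinematics), then returns the maximum of each resultant.
#'
#' @param lin Triaxial linear acceleration, unit `"g"`.
#' @param ang_acc Triaxial angular acceleration, unit `"rad_s2"`, or `NULL`.
#' @param ang_vel Triaxial angular velocity, unit `"rad_s"`, or `NULL`.
#' @param cutoff Low-pass cutoff in Hz applied channel-wise before the
#'   resultant is taken.
#' @return A list with `peak_lin_g`, `peak_ang_acc_rad_s2`,
#'   `peak_ang_vel_rad_s` (the latter two `NA` when the input is `NULL`).
#' @export
peak_metrics <- function(lin, ang_acc = NULL, ang_vel = NULL, cutoff = 180) {
  filt_resultant_max <- function(tr) {
    fx <- butterworth_filtfilt(tr$x, cutoff)
    fy <- butterworth_filtfilt(tr$y, cutoff)
    fz <- butterworth_filtfilt(tr$z, cutoff)
    max(resultant(triax_signal(fx, fy, fz))$samples)
  }
  if (!inherits(lin, "triax_signal"))
    stop("`lin` must be a triax_signal", call. = FALSE)
  list(
    peak_lin_g = filt_resultant_max(lin),
    peak_ang_acc_rad_s2 =
      if (is.null(ang_acc)) NA_real_ else filt_resultant_max(ang_acc),
    peak_ang_vel_rad_s =
      if (is.null(ang_vel)) NA_real_ else filt_resultant_max(ang_vel)
  )
}
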
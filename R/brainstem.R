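#' Superior-colliculus step command
#'
#' The collicular drive is reduced to a dummy unit whose firing rate equals
#' the desired saccade amplitude (1 Hz per degree). Only rightward
#' (positive) horizontal targets are modeled.
#'
#' @param target_amplitude desired displacement (deg), must be >= 0.
#' @return the drive `y_d` in Hz-equivalent units (numerically equal to the
#'   amplitude in degrees).
#' @export
sc_command <- function(target_amplitude) {
  if (any(target_amplitude < 0)) {
    stop("only rightward (nonnegative) saccade targets are modeled")
  }
  target_amplitude
}

#' Burst-generator output
#'
#' Grouped medium-lead burst neuron block. The burst magnitude is a
#' saturating function of the dynamic motor error, i.e. the desired
#' displacement plus the cerebellar correction minus the displacement
#' integrator's running estimate:
#' `u = A * scale * (1 - exp(-(y_c + y_d - D) / sigma))`,
#' rectified at zero (burst neurons cannot fire negatively; braking drive
#' is carried by the ipsilateral fastigial pathway instead). While the
#' eye-hold switch is active the burst is silenced.
#'
#' @param y_d desired-displacement drive (from [sc_command()]).
#' @param y_c net cerebellar contribution (drive units).
#' @param D displacement-integrator state (deg-equivalent drive).
#' @param A burst amplitude (Hz).
#' @param sigma slope constant.
#' @param motivation_scale multiplier on `A` in (0, 1]; models reduced
#'   motivational drive.
#' @param hold_active logical; `TRUE` silences the burst.
#' @return burst rate `u` (Hz), in `[0, A * motivation_scale)`.
#' @export
#' @examples
#' burst_output(20, 0, 0, A = 1100, sigma = 16)  # ~784.84 Hz
burst_output <- function(y_d, y_c, D, A, sigma, motivation_scale = 1,
                         hold_active = FALSE) {
  if (motivation_scale <= 0 || motivation_scale > 1) {
    stop("motivation_scale must lie in (0, 1]")
  }
  if (isTRUE(hold_active)) return(0)
  max(0, A * motivation_scale * (1 - exp(-(y_c + y_d - D) / sigma)))
}

#' Displacement-integrator step
#'
#' Imperfect integration of the burst output: `D <- D + k * u * dt`. The
#' imperfection is realized purely through the gain `k < 1` (a perfect
#' integral, scaled), closing the local feedback loop around the burst
#' generator. `k = 0` never closes the loop (the burst, and hence the eye
#' position, keeps growing); `k = 1` reaches the commanded displacement
#' but with much lower eye speed.
#'
#' @param D current integrator state.
#' @param u burst rate (Hz).
#' @param k integrator gain in \[0, 1\].
#' @param dt step size (s).
#' @return the updated integrator state.
#' @export
integrator_step <- function(D, u, k, dt) {
  stopifnot(dt > 0)
  D + k * u * dt
}

#' Eye-hold switch
#'
#' Replaces omnipause-neuron gating: a fixed time `cutoff_after_onset`
#' after detected movement onset, all brainstem and vermal inputs are cut
#' off and the eye is held at the reached position. Latching (once `TRUE`,
#' stays `TRUE`) is the caller's responsibility across a trial; this
#' predicate is pure.
#'
#' @param onset_time detected movement-onset time (s), or `NA` if the
#'   movement has not started.
#' @param t current time (s).
#' @param cutoff_after_onset switch delay after onset (s).
#' @return logical: is the hold active at time `t`?
#' @export
hold_switch <- function(onset_time, t, cutoff_after_onset) {
  if (is.null(onset_time) || is.na(onset_time)) return(FALSE)
  t >= onset_time + cutoff_after_onset
}
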
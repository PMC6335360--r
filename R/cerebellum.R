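#' Target-related mossy-fiber rate
#'
#' Long-lead buildup before movement initiation followed by a sustained
#' plateau: for `t <= t_on` the rate is
#' `lam * y_d * exp(-(t - t_on)^2 / alpha^2)`, from `t_on` it sustains at
#' `lam * y_d`, and it is silenced by the eye-hold switch.
#'
#' @param t time (s); vectorized.
#' @param t_on movement-initiation time (s).
#' @param y_d desired displacement (deg).
#' @param lam gain (Hz per degree).
#' @param alpha buildup spread (s).
#' @param hold_active logical; `TRUE` silences the channel.
#' @return mossy-fiber rate (Hz).
#' @export
mf_target_rate <- function(t, t_on, y_d, lam, alpha, hold_active = FALSE) {
  if (isTRUE(hold_active)) return(0 * t)
  peak <- lam * y_d
  ifelse(t <= t_on, peak * exp(-(t - t_on)^2 / alpha^2), peak)
}

#' Burst-related mossy-fiber rate
#'
#' Efference copy of the brainstem burst during the movement; silenced by
#' the eye-hold switch.
#'
#' @param u burst rate (Hz), nonnegative.
#' @param hold_active logical.
#' @return mossy-fiber rate (Hz).
#' @export
mf_burst_rate <- function(u, hold_active = FALSE) {
  if (isTRUE(hold_active)) return(0 * u)
  u
}

#' Normalize the mossy-fiber channels
#'
#' The two channels live on very different scales (target rates of tens of
#' Hz, burst rates of hundreds). Both are brought into \[0, 1\] before the
#' mossy-fiber-to-granule weights: the target channel by its largest
#' plateau `lam * 20` (20 deg is the top of the modeled target range), the
#' burst channel by the nominal burst amplitude `A`. Normalizing the burst
#' by the *nominal* `A` (not the motivation-scaled one) is essential: a
#' reduced-motivation burst must look smaller to the vermis.
#'
#' @param u_target target-channel rate (Hz).
#' @param u_burst burst-channel rate (Hz).
#' @param lam target mossy-fiber gain.
#' @param A nominal burst amplitude (Hz).
#' @return numeric length-2 vector `(target, burst)` in \[0, 1\].
#' @export
mf_normalize <- function(u_target, u_burst, lam, A) {
  c(u_target / (lam * 20), u_burst / A)
}

#' Granule activation function
#'
#' Saturating logistic with unit slope, scaled to `[0, f_max]`:
#' `f(x) = f_max / (1 + exp(-x))`.
#'
#' @param x net synaptic drive.
#' @param f_max saturation level (rate units).
#' @return activation in `(0, f_max)`.
#' @export
logistic_rate <- function(x, f_max = 1) {
  f_max / (1 + exp(-x))
}

#' Granular-layer reservoir step
#'
#' Rate-based leaky-integrator granule units with sparse random recurrent
#' inhibition: `tau * dz/dt = -z + S`, rectified at zero, with net drive
#' `S = f(w_mf_grc %*% mf - rho * w_rec %*% z)`. One forward-Euler step of
#' size `dt`.
#'
#' @param z granule activity vector (length N, nonnegative).
#' @param mf normalized mossy-fiber vector (length 2, from
#'   [mf_normalize()]).
#' @param w_mf_grc N x 2 input weight matrix.
#' @param w_rec N x N nonnegative recurrent matrix (unit spectral radius).
#' @param tau time constant (s).
#' @param rho spectral radius applied to the recurrent term.
#' @param dt step size (s), must satisfy `dt < tau`.
#' @param f_max saturation of the activation function.
#' @return the updated activity vector.
#' @export
reservoir_step <- function(z, mf, w_mf_grc, w_rec, tau, rho, dt, f_max = 1) {
  stopifnot(dt < tau)
  S <- logistic_rate(as.numeric(w_mf_grc %*% mf) -
                       rho * as.numeric(w_rec %*% z), f_max)
  pmax(0, z + (dt / tau) * (-z + S))
}

#' Resting fixed point of the granular layer
#'
#' With silent mossy fibers the granule activities relax to the solution
#' of `z = f(-rho * w_rec %*% z)`. Each trial starts from this baseline
#' (inter-trial intervals are long relative to `tau`). Solved by damped
#' fixed-point iteration.
#'
#' @param w_rec N x N nonnegative recurrent matrix.
#' @param rho spectral radius.
#' @param f_max saturation of the activation function.
#' @param tol convergence tolerance on the sup-norm update.
#' @param max_iter iteration cap.
#' @return the baseline activity vector.
#' @export
reservoir_baseline <- function(w_rec, rho, f_max = 1, tol = 1e-12,
                               max_iter = 10000L) {
  z <- rep(f_max / 2, nrow(w_rec))
  for (i in seq_len(max_iter)) {
    z_new <- z + 0.5 * (logistic_rate(-rho * as.numeric(w_rec %*% z), f_max) - z)
    if (max(abs(z_new - z)) < tol) return(pmax(0, z_new))
    z <- z_new
  }
  warning("reservoir baseline iteration did not reach tol; returning last iterate")
  pmax(0, z)
}

#' Purkinje-layer population activity
#'
#' The modeled Purkinje layer is the *total* population projection onto
#' one fastigial nucleus, not an individual cell: a single weighted sum of
#' all parallel fibers, `y_pc = w_pf_pc . z`.
#'
#' @param z granule activity vector.
#' @param w_pf_pc readout weight vector of matching length.
#' @return scalar population activity (rate units).
#' @export
pc_population_activity <- function(z, w_pf_pc) {
  if (length(z) != length(w_pf_pc)) {
    stop("granule vector and readout weights differ in length (",
         length(z), " vs ", length(w_pf_pc), ")")
  }
  sum(w_pf_pc * z)
}

#' Caudal fastigial nucleus activity
#'
#' Inhibitory Purkinje input combined with excitatory mossy-fiber drive
#' from the burst generator: `y_cfn = -w_pc_cfn * y_pc + w_mf_cfn * u`.
#'
#' @param y_pc Purkinje-layer population activity.
#' @param u brainstem burst rate (Hz).
#' @param w_pc_cfn Purkinje-to-fastigial strength (positive; the minus
#'   sign encodes the inhibition).
#' @param w_mf_cfn mossy-fiber-to-fastigial strength.
#' @return fastigial activity (rate units, signed relative to baseline 0).
#' @export
cfn_activity <- function(y_pc, u, w_pc_cfn, w_mf_cfn) {
  -w_pc_cfn * y_pc + w_mf_cfn * u
}

#' Net cerebellar contribution to the brainstem
#'
#' `y_c = r1 * y_cfn_contra + r2 * y_cfn_ipsi`. With the default gains
#' r1 = 0.02, r2 = -0.02 this is 0.02 times the contra-minus-ipsi
#' difference: the contralateral nucleus adds drive, the ipsilateral one
#' brakes.
#'
#' @param ycfn_contra,ycfn_ipsi fastigial activities.
#' @param r1,r2 responsibility gains.
#' @return the net correction in burst-drive units.
#' @export
net_cerebellar_output <- function(ycfn_contra, ycfn_ipsi, r1, r2) {
  r1 * ycfn_contra + r2 * ycfn_ipsi
}
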
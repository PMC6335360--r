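#' Discretize the oculomotor plant
#'
#' The eye plant is the second-order linear system
#' `k1 * theta'' + k2 * theta' + k3 * theta = m(t)` with motor drive `m`.
#' With the default constants (0.003, 0.6, 4) the characteristic roots are
#' about -6.9 and -193 1/s: overdamped, no ringing.
#'
#' The default integration scheme is the exact zero-order-hold
#' discretization of the companion-form state system over one step:
#' `x(t+dt) = Ad x(t) + Bd m(t)` with `Ad = expm(Ac dt)` and
#' `Bd = Ac^{-1} (Ad - I) Bc`, precomputed once per `dt`. This is
#' unconditionally stable at any step size.
#'
#' @param k1,k2,k3 plant coefficients (s^2, s, dimensionless).
#' @param dt step size (s).
#' @return a list with the 2x2 matrix `Ad` and length-2 vector `Bd`;
#'   state ordering is `(theta, theta_dot)`.
#' @export
plant_discretization <- function(k1, k2, k3, dt) {
  stopifnot(k1 > 0, dt > 0)
  Ac <- matrix(c(0, -k3 / k1, 1, -k2 / k1), 2, 2)
  Bc <- c(0, 1 / k1)
  e <- eigen(Ac)
  # expm via eigendecomposition; roots may be complex for underdamped plants
  Ad <- e$vectors %*% diag(exp(e$values * dt)) %*% solve(e$vectors)
  Ad <- matrix(Re(Ad), 2, 2)
  Bd <- solve(Ac, (Ad - diag(2)) %*% Bc)
  list(Ad = Ad, Bd = as.numeric(Bd))
}

#' Advance the plant one step (exact discretization)
#'
#' @param state numeric length-2 `(theta, theta_dot)` in deg and deg/s.
#' @param m motor drive held constant over the step.
#' @param disc discretization from [plant_discretization()].
#' @return the updated state.
#' @export
plant_step <- function(state, m, disc) {
  as.numeric(disc$Ad %*% state + disc$Bd * m)
}

#' Advance the plant one step (forward Euler)
#'
#' Reference scheme used for cross-checking the exact discretization at
#' fine step sizes; not used by the simulator itself.
#'
#' @inheritParams plant_discretization
#' @param state numeric length-2 `(theta, theta_dot)`.
#' @param m motor drive.
#' @return the updated state.
#' @export
plant_step_euler <- function(state, m, k1, k2, k3, dt) {
  theta <- state[1]
  v <- state[2]
  acc <- (m - k2 * v - k3 * theta) / k1
  c(theta + dt * v, v + dt * acc)
}

#' Clamp the eye at its current position
#'
#' Applied when the eye-hold switch fires: the position is kept and the
#' velocity zeroed; subsequent plant steps are bypassed while the hold is
#' active. Idempotent.
#'
#' @param state numeric length-2 `(theta, theta_dot)`.
#' @return `(theta, 0)`.
#' @export
clamp_position <- function(state) {
  c(state[1], 0)
}
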
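#' Instantaneous flight state of a bird
#'
#' Position, velocity, acceleration, roll angle and roll rate in a
#' right-handed inertial frame with z pointing up. The body axes follow
#' from the state: the roll axis `e_x'` is aligned with the velocity
#' (perfect pitch/yaw stability), and the pitch/yaw axes are the
#' wings-level datum rotated by the bank angle `Omega` about `e_x'`.
#'
#' @param r Position (length-3 numeric, m).
#' @param v Velocity (length-3 numeric, m s^-1); must be non-zero.
#' @param a Acceleration (length-3 numeric, m s^-2).
#' @param Omega Bank (roll) angle (rad).
#' @param omega Roll rate (rad s^-1).
#' @param prev_ey Previous lateral axis, used as the datum fallback when
#'   the velocity is vertical.
#' @return An object of class `bird_state`.
#' @export
bird_state <- function(r, v, a = c(0, 0, 0), Omega = 0, omega = 0,
                       prev_ey = NULL) {
  r <- as.numeric(r); v <- as.numeric(v); a <- as.numeric(a)
  stopifnot(length(r) == 3, length(v) == 3, length(a) == 3)
  if (sqrt(sum(v^2)) <= 0) stop("velocity must be non-zero", call. = FALSE)
  st <- list(r = r, v = v, a = a, Omega = Omega, omega = omega)
  st$axes <- body_axes(v, Omega, prev_ey)
  class(st) <- "bird_state"
  st
}

#' Body axes from velocity and bank angle
#'
#' The roll axis is `e_x' = v / |v|`. The wings-level datum puts the yaw
#' axis `e_z'` in the plane of `e_x'` and world-up (lateral axis
#' horizontal); when the velocity is vertical that plane is undefined and
#' the previous lateral axis is reused. The datum is then rotated by
#' `Omega` about `e_x'`, giving an orthonormal right-handed triad.
#'
#' @inheritParams bird_state
#' @return List with unit vectors `ex`, `ey`, `ez`.
#' @export
body_axes <- function(v, Omega = 0, prev_ey = NULL) {
  ex <- v / sqrt(sum(v^2))
  up <- c(0, 0, 1)
  ey0 <- vcross(up, ex)
  ny <- sqrt(sum(ey0^2))
  if (ny < 1e-9) {
    if (is.null(prev_ey)) prev_ey <- c(0, 1, 0)
    ey0 <- prev_ey - sum(prev_ey * ex) * ex
    ny <- sqrt(sum(ey0^2))
    if (ny < 1e-9) ey0 <- c(0, 1, 0) else ey0 <- ey0 / ny
  } else ey0 <- ey0 / ny
  ez0 <- vcross(ex, ey0)
  ey <- cos(Omega) * ey0 + sin(Omega) * ez0
  ez <- -sin(Omega) * ey0 + cos(Omega) * ez0
  list(ex = ex, ey = ey, ez = ez)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Total flight force
#'
#' Thrust-minus-drag acts along the roll axis, lift along the yaw axis,
#' and weight straight down: `F = TD e_x' + L e_z' - m g e_z`.
#'
#' @param state A [bird_state()].
#' @param TD Net thrust-minus-drag (N).
#' @param L Lift (N).
#' @param m Mass (kg).
#' @param g Gravitational acceleration (m s^-2).
#' @return Length-3 force vector (N).
#' @export
flight_force <- function(state, TD, L, m, g = 9.81) {
  TD * state$axes$ex + L * state$axes$ez - m * g * c(0, 0, 1)
}

#' Velocity-Verlet translation step
#'
#' `r(t+dt) = r + v dt + a dt^2 / 2`, then the new acceleration
#' `a(t+dt) = F/m` (force held over the step), then
#' `v(t+dt) = v + (a(t) + a(t+dt)) dt / 2`. Exact for constant
#' acceleration; body axes are recomputed from the new velocity at the
#' carried bank angle.
#'
#' @param state A [bird_state()].
#' @param force Length-3 force vector at the new time (N).
#' @param m Mass (kg).
#' @param dt Time step (s), positive.
#' @return Updated `bird_state`.
#' @export
step_translation <- function(state, force, m, dt) {
  stopifnot(dt > 0, m > 0)
  a_new <- force / m
  r <- state$r + state$v * dt + 0.5 * state$a * dt^2
  v <- state$v + 0.5 * (state$a + a_new) * dt
  if (sqrt(sum(v^2)) < 1e-9)
    stop("integration stalled: velocity collapsed to zero", call. = FALSE)
  bird_state(r, v, a_new, state$Omega, state$omega,
             prev_ey = state$axes$ey)
}

#' Explicit-Euler roll step
#'
#' `Omega(t+dt) = Omega + omega dt`, `omega(t+dt) = omega + (M/I) dt`.
#' The bank angle advances with the old rate, then the rate is updated —
#' the ordering that keeps a bang-bang maneuver time-symmetric.
#'
#' @param state A [bird_state()].
#' @param M_roll Roll torque (N m).
#' @param I_roll Roll inertia (kg m^2), positive.
#' @param dt Time step (s), positive.
#' @return Updated `bird_state`.
#' @export
step_roll <- function(state, M_roll, I_roll, dt) {
  stopifnot(dt > 0)
  if (I_roll <= 0) stop("roll inertia must be positive", call. = FALSE)
  Omega <- state$Omega + state$omega * dt
  omega <- state$omega + (M_roll / I_roll) * dt
  bird_state(state$r, state$v, state$a, Omega, omega,
             prev_ey = state$axes$ey)
}
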
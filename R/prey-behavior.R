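#' Prey forcing-function parameters
#'
#' The model-starling is driven open-loop by one of three forcing
#' functions (it does not react to the falcon):
#' \describe{
#'   \item{straight}{turn onto a fixed random heading (elevation within
#'     +/- 2.5 degrees) and hold it;}
#'   \item{smooth}{harmonically modulated centripetal acceleration to one
#'     side, plus an altitude-restoring vertical term;}
#'   \item{nonsmooth}{jinking — near-maximal acceleration along a
#'     direction that is re-drawn at random times (about 80 switches per
#'     second), plus the altitude-restoring term.}
#' }
#' The constants `c1..c9` are the calibrated settings that maximize the
#' prey's accelerations subject to roll-rate, isotropy and +/- 20 m
#' altitude-band constraints. `c5` is a per-reference-step (1e-4 s)
#' switch probability; the engine rescales it with the integration step so
#' the switching rate is step-size invariant.
#'
#' @param mode One of `"straight"`, `"smooth"`, `"nonsmooth"`.
#' @param c1,c2,c3,c4,c5,c6,c7,c8,c9 Forcing constants (defaults are the
#'   calibrated settings). `c3` is the exponent shaping the smooth-mode
#'   modulation; `c9` is in degrees.
#' @return An object of class `prey_params`.
#' @export
prey_params <- function(mode = c("nonsmooth", "smooth", "straight"),
                        c1 = 0.7, c2 = 3.5, c3 = 0.13, c4 = 1.5,
                        c5 = 0.008, c6 = 0.99, c7 = 1.6, c8 = 0.1,
                        c9 = 20) {
  mode <- match.arg(mode)
  structure(list(mode = mode, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 c5 = c5, c6 = c6, c7 = c7, c8 = c8, c9 = c9),
            class = "prey_params")
}

#' Attainable normal acceleration of the prey
#'
#' The largest lift per unit mass the morphology can produce at the given
#' airspeed, over both flight modes. Forcing functions scale their
#' commands by this quantity so the prey always demands (near-)attainable
#' maneuvers.
#'
#' @inheritParams friction_drag_coeff
#' @return Maximum normal acceleration (m s^-2).
#' @export
max_normal_acceleration <- function(v, morph, consts = flight_constants()) {
  max(max_lift_flapping(v, morph, consts),
      max_lift_gliding(v, morph, consts)$L_max) / morph$m_total
}

#' Straight-flight forcing command
#'
#' Steers the velocity toward a fixed target direction: the command is the
#' component of the target direction perpendicular to the current
#' velocity, scaled to the largest magnitude whose combination with weight
#' support stays within the attainable normal acceleration, and ramped
#' down near alignment to avoid chatter.
#'
#' @param state A [bird_state()].
#' @param target_dir Fixed unit heading chosen at engagement start.
#' @param a_max Attainable normal acceleration (m s^-2) at current speed.
#' @param g Gravitational acceleration (m s^-2).
#' @return Commanded acceleration (length-3, m s^-2).
#' @export
straight_command <- function(state, target_dir, a_max, g = 9.81) {
  vhat <- state$v / sqrt(sum(state$v^2))
  perp <- target_dir - sum(target_dir * vhat) * vhat
  np <- sqrt(sum(perp^2))
  if (np < 1e-12) return(c(0, 0, 0))
  u <- perp / np
  ang <- asin(min(1, np))
  if (sum(target_dir * vhat) < 0) ang <- pi - ang
  # largest s with |s u + g ez| <= a_max
  uz <- u[3]
  disc <- (g * uz)^2 + a_max^2 - g^2
  s_cap <- if (disc <= 0) 0 else -g * uz + sqrt(disc)
  s <- s_cap * min(1, ang / 0.1)
  s * u
}

#' Smooth-maneuver forcing command
#'
#' Harmonic lateral forcing: `a* = h (c1 sin(c2 t) + c1)^c3 a_max +
#' c4 kappa e_z`, where `h = e_x' x e_z / |e_x' x e_z|` is horizontal and
#' perpendicular to the velocity, and `kappa` is the height of the start
#' altitude above the current one (the restoring term holds the bird in a
#' +/- 20 m band). The exponent `c3` produces a near-saturating, smoothly
#' pulsing command whose long-run mean load factor is about 3.4.
#'
#' @param t Time since engagement start (s).
#' @param state A [bird_state()].
#' @param params A [prey_params()].
#' @param a_max Attainable normal acceleration (m s^-2).
#' @param kappa Start altitude minus current altitude (m).
#' @param h_prev Fallback lateral direction when the velocity is vertical.
#' @return Commanded acceleration (length-3, m s^-2).
#' @export
smooth_command <- function(t, state, params, a_max, kappa,
                           h_prev = c(0, 1, 0)) {
  h <- vcross(state$axes$ex, c(0, 0, 1))
  nh <- sqrt(sum(h^2))
  h <- if (nh < 1e-9) h_prev else h / nh
  lateral <- (params$c1 * sin(params$c2 * t) + params$c1)^params$c3 * a_max
  h * lateral + c(0, 0, params$c4 * kappa)
}

#' Non-smooth (jinking) forcing command
#'
#' `a* = q c6 a_max + c7 kappa e_z` with `q` the current random unit
#' direction; see [update_prey_direction()] for the switching process.
#'
#' @inheritParams smooth_command
#' @param q Current random unit direction.
#' @return Commanded acceleration (length-3, m s^-2).
#' @export
nonsmooth_command <- function(state, params, q, a_max, kappa) {
  q * params$c6 * a_max + c(0, 0, params$c7 * kappa)
}

#' Random direction switching for jinking prey
#'
#' With probability `p_switch` the direction becomes the renormalized
#' blend `c8 q + (1 - c8) Q`, where `Q` points toward a uniform random
#' azimuth with elevation uniform in +/- `c9` degrees. Otherwise `q` is
#' unchanged.
#'
#' @param q Current unit direction.
#' @param params A [prey_params()].
#' @param p_switch Switch probability for this step (defaults to `c5`,
#'   the per-reference-step value).
#' @return Updated unit direction.
#' @export
update_prey_direction <- function(q, params, p_switch = params$c5) {
  if (stats::runif(1) >= p_switch) return(q)
  el <- stats::runif(1, -params$c9, params$c9) * pi / 180
  az <- stats::runif(1, 0, 2 * pi)
  Q <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  q_new <- params$c8 * q + (1 - params$c8) * Q
  q_new / sqrt(sum(q_new^2))
}

#' Long-run prey flight statistics
#'
#' Runs the prey alone under its forcing function (full closed-loop
#' dynamics and control, no falcon) and summarizes the maneuvering it
#' actually achieves: mean load factor (lift over weight), mean absolute
#' roll acceleration, the altitude band visited, and mean airspeed.
#'
#' @param morph Prey [bird_morphology()].
#' @param params A [prey_params()].
#' @param consts A [flight_constants()].
#' @param duration Simulated time (s).
#' @param dt Integration step (s).
#' @param seed RNG seed.
#' @param keep_commands Return the per-sample lateral command directions
#'   (for isotropy checks).
#' @return A list with `mean_load_factor`, `mean_abs_roll_accel`
#'   (rad s^-2), `altitude_range` (m, relative to start), `mean_speed`,
#'   and optionally `commands` (matrix of horizontal command components).
#' @export
prey_flight_stats <- function(morph, params = prey_params(),
                              consts = flight_constants(),
                              duration = 100, dt = 1e-4, seed = 1,
                              keep_commands = FALSE) {
  set.seed(seed)
  res <- cpp_run_prey(morph_vec(morph), consts_vec(consts),
                      prey_vec(params), duration, dt, keep_commands)
  out <- list(mean_load_factor = res$mean_load_factor,
              mean_abs_roll_accel = res$mean_abs_roll_accel,
              altitude_range = res$altitude_range,
              mean_speed = res$mean_speed,
              final_v = res$final_v,
              target_dir = res$target_dir)
  if (keep_commands) out$commands <- res$commands
  out
}
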
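#' Gravity-compensated lift demand
#'
#' The guidance command is a desired total acceleration. Gravity acts on
#' the bird regardless, so the aerodynamic (lift) demand is the command
#' plus weight support, projected onto the plane spanned by the body's
#' lateral and dorsoventral axes (any component along the flight direction
#' is the thrust controller's job and is discarded here):
#' `a_proj = ((a* + g e_z) . e_y') e_y' + ((a* + g e_z) . e_z') e_z'`.
#' Its magnitude times mass is the lift demand; its direction is the roll
#' target.
#'
#' A `strict_sign` mode retains the alternative convention in which
#' gravity is subtracted rather than compensated (commanding a standing
#' downward bias); it exists for comparison only.
#'
#' @param a_star Commanded acceleration (length-3, m s^-2).
#' @param axes Body axes as returned by [body_axes()].
#' @param g Gravitational acceleration (m s^-2).
#' @param strict_sign Use `a* - g e_z` instead of `a* + g e_z`.
#' @return List with `a_proj` (length-3 vector in the body y'-z' plane,
#'   expressed in inertial coordinates), `ay` and `az` (its body-frame
#'   components), and `magnitude`.
#' @export
weight_support <- function(a_star, axes, g = 9.81, strict_sign = FALSE) {
  a_steer <- if (strict_sign) a_star - c(0, 0, g) else a_star + c(0, 0, g)
  ay <- sum(a_steer * axes$ey)
  az <- sum(a_steer * axes$ez)
  a_proj <- ay * axes$ey + az * axes$ez
  list(a_proj = a_proj, ay = ay, az = az,
       magnitude = sqrt(ay^2 + az^2))
}

#' Roll angle to the desired bank
#'
#' The signed roll, about the body's forward axis, that aligns the lift
#' axis `e_z'` with the projected acceleration demand:
#' `gamma = -atan2(a_proj . e_y', a_proj . e_z')`, in `(-pi, pi]`. Its
#' magnitude is the unsigned angle between demand and lift axis; the sign
#' follows from the right-handed axis convention (rolling by a positive
#' angle carries body-frame coordinates of a fixed vector the opposite
#' way). A vanishing demand gives `gamma = 0`.
#'
#' @param ws Output of [weight_support()] (or any list with `ay`, `az`,
#'   `magnitude`).
#' @return Signed roll angle to execute (rad).
#' @export
roll_target <- function(ws) {
  if (ws$magnitude <= 0) return(0)
  -atan2(ws$ay, ws$az)
}

#' Bang-bang roll command
#'
#' Minimum-time attitude control: accelerate maximally toward the target
#' bank offset `gamma`, switching to maximal deceleration at the point
#' from which maximal braking reaches `gamma` with zero residual rate.
#' The switching rule: the roll acceleration takes the sign of `gamma`,
#' unless the rate `omega` already has the sign of `gamma` and
#' `omega^2 > 2 |omega_dot_max| |gamma|` (braking now still reaches the
#' target), in which case it takes the opposite sign.
#'
#' @param gamma Signed angle to the desired bank (rad).
#' @param omega Current roll rate (rad s^-1).
#' @param max_accel Maximal roll acceleration available (rad s^-2),
#'   positive.
#' @return The sign (-1, 0, 1) to apply to `max_accel`.
#' @export
bang_bang_roll <- function(gamma, omega, max_accel) {
  if (max_accel <= 0) stop("max_accel must be positive", call. = FALSE)
  if (gamma == 0) return(-sign(omega))
  s <- sign(gamma)
  if (sign(omega) == s && omega^2 > 2 * max_accel * abs(gamma)) -s else s
}
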
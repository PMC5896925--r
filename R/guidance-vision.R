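#' Measure the line of sight with bounded angular error
#'
#' The attacker does not see the true relative position `r_d` but a
#' perturbed one: an error vector with magnitude drawn uniformly from
#' `[0, xi]` radians and direction uniform on the circle perpendicular to
#' the true line of sight is scaled by the range, giving
#' `r_hat = r_d + eps * |r_d|`. For small `xi` the angular deviation of
#' the measurement is at most about `xi`.
#'
#' @param r_d True relative position, attacker to target (length-3, m).
#' @param xi Visual error bound (rad); 0.007 rad is the model default
#'   (the minimum retinal image motion detectable over one 50 ms
#'   differencing interval).
#' @param mode `"circular"` (error confined to the plane perpendicular to
#'   the line of sight, the default) or `"solid"` (direction uniform over
#'   the error cone).
#' @return Measured relative position (length-3, m).
#' @export
measure_los <- function(r_d, xi = 0.007, mode = c("circular", "solid")) {
  mode <- match.arg(mode)
  range <- sqrt(sum(r_d^2))
  if (range <= 0) stop("zero range: engagement already terminated",
                       call. = FALSE)
  if (xi == 0) return(r_d)
  rhat <- r_d / range
  # orthonormal pair perpendicular to the line of sight
  ref <- if (abs(rhat[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- vcross(rhat, ref); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- vcross(rhat, u1)
  mag <- stats::runif(1, 0, xi)
  psi <- stats::runif(1, 0, 2 * pi)
  eps <- mag * (cos(psi) * u1 + sin(psi) * u2)
  if (mode == "solid") {
    # uniform over the spherical cap of half-angle xi, projected onto the
    # perpendicular plane
    cosang <- stats::runif(1, cos(xi), 1)
    eps <- tan(acos(cosang)) * (cos(psi) * u1 + sin(psi) * u2)
  }
  r_d + eps * range
}

#' Line-of-sight rate from two successive measurements
#'
#' Finite-difference estimate of the angular velocity of the line of
#' sight: the relative velocity is `(r_hat(t) - r_hat(t - tau)) / tau`
#' and the rate vector is `lambda_dot = r_hat x v_hat / |r_hat|^2`. The
#' guidance loop samples and holds this value every `tau` seconds.
#'
#' @param r_hat_now,r_hat_prev Measured relative positions `tau` apart.
#' @param tau Differencing (and sample-hold) interval (s), positive.
#' @return Line-of-sight angular velocity vector (rad s^-1).
#' @export
los_rate <- function(r_hat_now, r_hat_prev, tau) {
  stopifnot(tau > 0)
  d2 <- sum(r_hat_now^2)
  if (d2 <= 0) stop("zero range: engagement already terminated",
                    call. = FALSE)
  v_hat <- (r_hat_now - r_hat_prev) / tau
  vcross(r_hat_now, v_hat) / d2
}

#' Pure proportional navigation command
#'
#' The guidance law of the model-falcon: commanded acceleration
#' `a* = N lambda_dot x v`, which turns the attacker's velocity at `N`
#' times the angular rate of the line of sight and is perpendicular to the
#' velocity by construction. In the planar case this reduces to the
#' classic turn-rate law `gamma_dot = N lambda_dot`.
#'
#' @param lambda_dot Line-of-sight rate vector (rad s^-1).
#' @param v Attacker velocity (m s^-1).
#' @param N Navigation constant (dimensionless gain), positive.
#' @return Commanded acceleration (length-3, m s^-2), perpendicular to
#'   `v`.
#' @export
ppn_command <- function(lambda_dot, v, N) {
  if (N <= 0) stop("navigation constant must be positive", call. = FALSE)
  N * vcross(lambda_dot, v)
}
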
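# packing helpers: fixed-order parameter vectors consumed by the engine
morph_vec <- function(morph, cap_load = Inf, cap_rollacc = Inf) {
  c(morph$f, morph$l_w, morph$b_max, morph$b_min, morph$m_b, morph$m_w,
    morph$I_b, morph$I_wing, morph$J, morph$S_w_max, morph$AR_max,
    morph$theta, morph$S_b, morph$c_d_body, morph$c_d_fric_ref,
    morph$v_thresh, morph$c_l_max, morph$m_total, morph$L0,
    if (morph$friction == "blasius") 1 else 0, cap_load, cap_rollacc)
}

consts_vec <- function(consts) c(consts$rho, consts$g, consts$mu_air)

prey_vec <- function(params) {
  mode <- match(params$mode, c("straight", "smooth", "nonsmooth")) - 1
  c(mode, params$c1, params$c2, params$c3, params$c4, params$c5,
    params$c6, params$c7, params$c8, params$c9)
}

#' Engagement configuration
#'
#' All parameters of one falcon-vs-prey encounter. Defaults are the
#' baseline model settings: the prey starts at the origin at 11 m s^-1 in
#' a random orientation; the falcon starts at the given horizontal offset
#' and altitude, flying at 16 m s^-1 straight at the prey with its lateral
#' axis horizontal. A catch occurs within 0.2 m; an unrecoverable
#' near-miss occurs when the falcon has come within 5 m, then finds itself
#' farther than that with the prey inside its rear 45-degree blind cone;
#' otherwise the attack times out after 40 s.
#'
#' @param N Navigation constant of the falcon's guidance law.
#' @param altitude Initial falcon altitude above the prey (m; may be
#'   negative).
#' @param horiz_dist Initial horizontal separation (m).
#' @param tau Visual differencing time and guidance sample-hold interval
#'   (s).
#' @param xi Visual error bound (rad) per differencing interval. The
#'   default `NULL` derives it from the underlying retinal-motion
#'   detection threshold of about 0.14 rad s^-1, i.e. `xi = 0.14 * tau`
#'   (0.007 rad at the baseline `tau` of 50 ms): the error bound is
#'   physically a rate threshold, so it shrinks with the differencing
#'   time. Supply a number to fix it independently of `tau`.
#' @param chi Control error parameter (0 = perfect control).
#' @param prey_mode Prey forcing mode, or a full [prey_params()].
#' @param dt Integration time step (s).
#' @param catch_radius,near_miss_radius,blind_cone_half_angle,timeout
#'   Termination rules (m, m, rad, s).
#' @param v0_prey,v0_falcon Initial speeds (m s^-1).
#' @param log_dt Trajectory decimation interval (s).
#' @param strict_sign Use the uncompensated gravity sign in weight support
#'   (comparison mode; see [weight_support()]).
#' @param error_mode Visual error geometry, `"circular"` or `"solid"`.
#' @return An object of class `engagement_config`.
#' @export
engagement_config <- function(N = 3, altitude = 300, horiz_dist = 400,
                              tau = 0.05, xi = NULL, chi = 0,
                              prey_mode = "nonsmooth", dt = 1e-4,
                              catch_radius = 0.2, near_miss_radius = 5.0,
                              blind_cone_half_angle = 45 * pi / 180,
                              timeout = 40, v0_prey = 11, v0_falcon = 16,
                              log_dt = 0.01, strict_sign = FALSE,
                              error_mode = c("circular", "solid")) {
  error_mode <- match.arg(error_mode)
  prey <- if (inherits(prey_mode, "prey_params")) prey_mode
          else prey_params(mode = prey_mode)
  if (is.null(xi)) xi <- 0.14 * tau
  stopifnot(N > 0, dt > 0, tau > 0, xi >= 0, chi >= 0, timeout > 0)
  structure(list(N = N, altitude = altitude, horiz_dist = horiz_dist,
                 tau = tau, xi = xi, chi = chi, prey = prey, dt = dt,
                 catch_radius = catch_radius,
                 near_miss_radius = near_miss_radius,
                 blind_cone_half_angle = blind_cone_half_angle,
                 timeout = timeout, v0_prey = v0_prey,
                 v0_falcon = v0_falcon, log_dt = log_dt,
                 strict_sign = strict_sign, error_mode = error_mode),
            class = "engagement_config")
}

config_vec <- function(cfg) {
  c(cfg$N, cfg$altitude, cfg$horiz_dist, cfg$tau, cfg$xi, cfg$chi, cfg$dt,
    cfg$catch_radius, cfg$near_miss_radius, cfg$blind_cone_half_angle,
    cfg$timeout, cfg$v0_prey, cfg$v0_falcon,
    max(1, round(cfg$log_dt / cfg$dt)),
    as.numeric(cfg$strict_sign),
    if (cfg$error_mode == "solid") 1 else 0,
    1e-4)
}

#' Run one falcon-vs-prey engagement
#'
#' Simulates a full encounter at the configured time step: the prey flies
#' its forcing function, the falcon measures the line of sight every
#' `tau` seconds (with angular error up to `xi`), commands pure
#' proportional navigation, and both birds resolve their guidance demands
#' through the flight controller and aerodynamics each step. Terminates on
#' catch, unrecoverable near-miss, or timeout.
#'
#' @param config An [engagement_config()].
#' @param falcon,prey [bird_morphology()] objects.
#' @param consts A [flight_constants()].
#' @param seed RNG seed (one engagement = one seed; identical seed and
#'   configuration reproduce the result exactly).
#' @param cap_load,cap_roll_accel Optional artificial caps on the falcon's
#'   lift (N) and roll acceleration (rad s^-2), used by the
#'   performance-capping experiment.
#' @return An object of class `engagement_result`: a list with `outcome`
#'   (`"catch"`, `"near_miss"`, `"timeout"`), `t_end`, `intercept_speed`,
#'   `min_distance`, `n_steps`, and `trajectory` (a decimated tibble).
#' @examples
#' \donttest{
#' run_engagement(engagement_config(altitude = 100, horiz_dist = 80,
#'                                  prey_mode = "straight"), seed = 1)
#' }
#' @export
run_engagement <- function(config = engagement_config(),
                           falcon = falcon_morphology(),
                           prey = starling_morphology(),
                           consts = flight_constants(), seed = 1,
                           cap_load = Inf, cap_roll_accel = Inf) {
  stopifnot(inherits(config, "engagement_config"))
  set.seed(seed)
  res <- cpp_run_engagement(morph_vec(falcon, cap_load, cap_roll_accel),
                            morph_vec(prey), consts_vec(consts),
                            prey_vec(config$prey), config_vec(config))
  traj <- tibble::as_tibble(as.data.frame(res$trajectory))
  names(traj) <- c("t", "distance", "falcon_speed", "falcon_accel",
                   "falcon_load", "falcon_bank", "prey_speed",
                   "prey_accel", "prey_load", "falcon_x", "falcon_y",
                   "falcon_z", "prey_x", "prey_y", "prey_z")
  structure(list(
    outcome = c("catch", "near_miss", "timeout")[res$outcome + 1],
    t_end = res$t_end,
    intercept_speed = res$intercept_speed,
    min_distance = res$min_distance,
    n_steps = res$n_steps,
    trajectory = traj,
    config = config, seed = seed),
    class = "engagement_result")
}

#' @export
print.engagement_result <- function(x, ...) {
  cat(sprintf("<engagement_result> %s at t = %.3f s (min distance %.3f m, intercept speed %.1f m/s)\n",
              x$outcome, x$t_end, x$min_distance, x$intercept_speed))
  invisible(x)
}

#' @rdname run_engagement
#' @param x An `engagement_result`.
#' @param ... Unused.
#' @export
tidy.engagement_result <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, t_end = x$t_end,
                 intercept_speed = x$intercept_speed,
                 min_distance = x$min_distance, n_steps = x$n_steps,
                 N = x$config$N, altitude = x$config$altitude,
                 horiz_dist = x$config$horiz_dist, seed = x$seed)
}

#' Plot an engagement trajectory
#'
#' Side view (horizontal range vs altitude) of the attacker and prey
#' paths, with the terminal point marked.
#'
#' @param object An `engagement_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.engagement_result <- function(object, ...) {
  tr <- object$trajectory
  d <- dplyr::bind_rows(
    tibble::tibble(bird = "falcon",
                   range = sqrt(tr$falcon_x^2 + tr$falcon_y^2),
                   z = tr$falcon_z),
    tibble::tibble(bird = "prey",
                   range = sqrt(tr$prey_x^2 + tr$prey_y^2), z = tr$prey_z))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$range, y = .data$z,
                                  colour = .data$bird)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "horizontal range (m)", y = "altitude (m)",
                  title = paste("outcome:", object$outcome))
}
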
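#' Flight performance envelope over an airspeed grid
#'
#' Summarizes what a morphology can do at each airspeed:
#' \describe{
#'   \item{level_accel}{Maximum level forward acceleration (m s^-2): best
#'     net thrust-minus-drag over flap/glide with lift pinned to weight;
#'     `NA` below the stall-support speed where weight cannot be carried.}
#'   \item{dive_accel}{Maximum vertical dive acceleration including gravity
#'     (m s^-2): gravity plus the best thrust-minus-drag at zero lift
#'     (flapping, or gliding with fully retracted wings, whichever is
#'     larger).}
#'   \item{load_factor}{Maximum attainable lift over weight.}
#'   \item{roll_accel}{Maximum roll acceleration (rad s^-2).}
#'   \item{turn_radius}{`v^2` over the maximum normal acceleration (m).}
#' }
#'
#' @param morph A [bird_morphology()].
#' @param consts A [flight_constants()].
#' @param speeds Strictly positive, increasing airspeed grid (m s^-1).
#' @return A tibble of class `performance_envelope`, one row per speed.
#' @examples
#' env <- performance_envelope(starling_morphology(), speeds = c(5, 10, 20))
#' env
#' @export
performance_envelope <- function(morph, consts = flight_constants(),
                                 speeds = seq(2, 130, by = 0.5)) {
  if (length(speeds) == 0) stop("empty speed grid", call. = FALSE)
  if (any(speeds <= 0) || is.unsorted(speeds, strictly = TRUE))
    stop("speeds must be positive and strictly increasing", call. = FALSE)
  m <- morph$m_total
  g <- consts$g
  rows <- purrr::map(speeds, function(v) {
    weight <- m * g
    can_level <- max(max_lift_flapping(v, morph, consts),
                     max_lift_gliding(v, morph, consts)$L_max) >= weight
    level <- if (can_level) {
      res <- resolve_forces(weight, v, morph, consts)
      res$TD / m
    } else NA_real_
    dive <- g + dive_td(v, morph, consts) / m
    L_max <- max(max_lift_flapping(v, morph, consts),
                 max_lift_gliding(v, morph, consts)$L_max)
    n_max <- L_max / weight
    a_norm <- L_max / m
    tibble::tibble(speed = v, level_accel = level, dive_accel = dive,
                   load_factor = n_max,
                   roll_accel = max_roll_acceleration(v, morph, consts)$omega_dot_max,
                   turn_radius = v^2 / a_norm)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("performance_envelope", class(out))
  attr(out, "species") <- morph$species
  out
}

# best zero-lift thrust-minus-drag (flap at full span vs glide fully
# retracted); used for the vertical dive branch of the envelope
dive_td <- function(v, morph, consts) {
  td_flap <- thrust_minus_drag(0, wing_config(morph, morph$b_max, TRUE),
                               v, morph, consts)
  td_glide <- thrust_minus_drag(0, wing_config(morph, morph$b_min, FALSE),
                                v, morph, consts)
  max(td_flap, td_glide)
}

#' Characteristic speeds of a morphology
#'
#' Solves the envelope for its three landmark speeds: the maximum sustained
#' level speed (zero crossing of maximum level acceleration), the terminal
#' speed of a vertical dive (zero crossing of dive acceleration), and the
#' minimum sustained level speed (slowest airspeed at which lift can still
#' match weight and level acceleration is non-negative).
#'
#' @inheritParams performance_envelope
#' @return A tibble with columns `quantity`, `speed` (m s^-1).
#' @examples
#' envelope_speeds(falcon_morphology())
#' @export
envelope_speeds <- function(morph, consts = flight_constants()) {
  m <- morph$m_total
  weight <- m * consts$g
  level_td <- function(v) resolve_forces(weight, v, morph, consts)$TD
  support <- function(v) max(max_lift_flapping(v, morph, consts),
                             max_lift_gliding(v, morph, consts)$L_max) - weight
  # slowest speed at which weight can be supported at all
  v_support <- stats::uniroot(support, c(0.5, 60), tol = 1e-10)$root
  # bracket the upper TD zero-crossing from a point of positive TD
  grid <- seq(v_support * 1.001, 80, length.out = 200)
  pos <- grid[purrr::map_dbl(grid, level_td) > 0]
  if (length(pos) == 0) stop("no sustainable level flight speed", call. = FALSE)
  v_max <- stats::uniroot(level_td, c(max(pos), 80), tol = 1e-10)$root
  dive <- function(v) consts$g + dive_td(v, morph, consts) / m
  v_term <- stats::uniroot(dive, c(10, 400), tol = 1e-10)$root
  # minimum sustained speed: lowest v with supportable weight and TD >= 0
  v_min <- if (level_td(v_support * 1.001) >= 0) v_support else
    stats::uniroot(level_td, c(v_support * 1.001, min(pos)),
                   tol = 1e-10)$root
  tibble::tibble(
    quantity = c("max_level_speed", "terminal_dive_speed",
                 "min_sustained_speed"),
    speed = c(v_max, v_term, v_min))
}

#' Plot a performance envelope
#'
#' Faceted curves of level acceleration, dive acceleration, load factor,
#' roll acceleration and turning radius against airspeed, mirroring the
#' standard flight-performance panel layout.
#'
#' @param object A `performance_envelope` (or a row-bound set of them).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.performance_envelope <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"speed",
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$speed, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "airspeed (m/s)", y = NULL,
                  title = attr(object, "species"))
}
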
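#' Wing configuration at a given span
#'
#' Wing area shrinks linearly with span between full extension and full
#' retraction, `S_w = S_w_max (b - b_min) / (b_max - b_min)`, and the
#' aspect ratio follows as `AR = b^2 / S_w`. At `b = b_min` the wing area
#' vanishes; the aspect ratio is then undefined and all span-dependent drag
#' terms are zero, so `AR` is reported as `NA` and never used.
#'
#' @param morph A [bird_morphology()] object.
#' @param b Wing span (m), in `[b_min, b_max]`.
#' @param flapping Logical; flapping (at max wingbeat frequency) or gliding.
#' @return A list of class `wing_config` with fields `b`, `S_w`, `AR`,
#'   `flapping`, `f_eff`.
#' @export
wing_config <- function(morph, b, flapping = FALSE) {
  stopifnot(inherits(morph, "bird_morphology"))
  if (b < morph$b_min - 1e-12 || b > morph$b_max + 1e-12)
    stop("span outside [b_min, b_max]", call. = FALSE)
  b <- min(max(b, morph$b_min), morph$b_max)
  S_w <- morph$S_w_max * (b - morph$b_min) / (morph$b_max - morph$b_min)
  AR <- if (S_w > 0) b^2 / S_w else NA_real_
  structure(list(b = b, S_w = S_w, AR = AR, flapping = flapping,
                 f_eff = if (flapping) morph$f else 0),
            class = "wing_config")
}

#' Torque-limit coefficient on flapping thrust
#'
#' Sustainable muscle torque caps flapping thrust above a species-specific
#' airspeed: `c_torque = min(1, v_thresh / v)`. Multiplying thrust by this
#' factor keeps thrust power approximately constant above `v_thresh`.
#'
#' @param v Airspeed (m s^-1), positive.
#' @param v_thresh Torque-constraint speed (m s^-1).
#' @return Coefficient in `(0, 1]`.
#' @export
c_torque <- function(v, v_thresh) {
  if (any(v <= 0)) stop("airspeed must be positive", call. = FALSE)
  pmin(1, v_thresh / v)
}

# mean-square flapping speed of the wing over a beat (elliptical planform,
# sinusoidal stroke); used to augment the lift-generating dynamic pressure
# while flapping. Zero when gliding.
flap_speed_sq <- function(morph) {
  0.5 * (pi * morph$f * sin(morph$theta / 2) * morph$l_w)^2
}

#' Wing friction drag coefficient
#'
#' In `"blasius"` mode, the laminar flat-plate boundary layer solution
#' `c_d_fric = 2 * 1.328 / sqrt(Re)` (both wing surfaces) with
#' `Re = rho v chord / mu_air` and mean chord `S_w / b`. In `"fixed"` mode
#' (the default set on the morphology) the species reference constant is
#' returned. A degenerate wing (`S_w = 0`) falls back to the reference
#' constant in either mode; the coefficient then multiplies zero area.
#'
#' @param v Airspeed (m s^-1), positive.
#' @param wing A [wing_config()].
#' @param morph A [bird_morphology()].
#' @param consts A [flight_constants()].
#' @param mode Override of `morph$friction` (`"fixed"` or `"blasius"`).
#' @return Friction drag coefficient (dimensionless).
#' @export
friction_drag_coeff <- function(v, wing, morph, consts = flight_constants(),
                                mode = morph$friction) {
  if (v <= 0) stop("airspeed must be positive", call. = FALSE)
  mode <- match.arg(mode, c("fixed", "blasius"))
  if (mode == "fixed" || wing$S_w <= 0) return(morph$c_d_fric_ref)
  chord <- wing$S_w / wing$b
  Re <- consts$rho * v * chord / consts$mu_air
  2 * (1.328 / sqrt(Re))
}

#' Maximum achievable lift in gliding flight
#'
#' In a glide the bird retracts its wings to trade stall-limited lift
#' (which grows with span through wing area) against the muscle torque
#' limit (which tightens with span through the moment arm). The
#' lift-maximizing span is
#' `b_ml = (b_max - b_min) sqrt(L0 / (0.5 rho S_w_max c_l_max v^2)) + b_min`,
#' clipped to `[b_min, b_max]`; the attainable lift is the stall-limited
#' lift at that span, additionally capped at `L0` when the span clips at
#' full extension (slow flight, where the torque bound is inactive).
#'
#' @inheritParams friction_drag_coeff
#' @return A list with `L_max` (N) and `b_ml` (m).
#' @export
max_lift_gliding <- function(v, morph, consts = flight_constants()) {
  if (v <= 0) stop("airspeed must be positive", call. = FALSE)
  q_max <- 0.5 * consts$rho * morph$S_w_max * morph$c_l_max * v^2
  b_ml <- (morph$b_max - morph$b_min) * sqrt(morph$L0 / q_max) + morph$b_min
  clipped_high <- b_ml >= morph$b_max
  b_ml <- min(max(b_ml, morph$b_min), morph$b_max)
  S_ml <- morph$S_w_max * (b_ml - morph$b_min) / (morph$b_max - morph$b_min)
  L_max <- 0.5 * consts$rho * S_ml * morph$c_l_max * v^2
  if (clipped_high) L_max <- min(morph$L0, L_max)
  list(L_max = L_max, b_ml = b_ml)
}

#' Maximum achievable lift in flapping flight
#'
#' Flapping uses full span, so the torque limit caps lift at `L0`. The
#' stall limit is evaluated against the wingbeat-averaged dynamic pressure
#' `0.5 rho S_w_max (v^2 + U_f^2)`, where `U_f^2` is the mean-square
#' flapping speed of the wing: at low airspeed the beating wing itself
#' supplies most of the lift-generating airflow.
#'
#' @inheritParams friction_drag_coeff
#' @return Maximum lift while flapping (N).
#' @export
max_lift_flapping <- function(v, morph, consts = flight_constants()) {
  if (v <= 0) stop("airspeed must be positive", call. = FALSE)
  stall <- 0.5 * consts$rho * morph$S_w_max * morph$c_l_max *
    (v^2 + flap_speed_sq(morph))
  min(morph$L0, stall)
}

#' Wingbeat-averaged net thrust minus drag
#'
#' The central force law of the model. When flapping (full span, maximum
#' wingbeat frequency):
#' \deqn{TD = (1 - c_l^2/c_{l.max}^2)\,\frac{\pi^3}{16}\rho b^2
#'   \sin^2(\theta/2) f^2 l_w^2 c_{torque}
#'   - (c_{d.body}S_b + c_{d.fric}S_w)\,\tfrac12\rho v^2
#'   - \frac{c_l^2 S_w \rho u^2}{2\pi AR}}
#' where the lift coefficient is referenced to the flapping-augmented
#' dynamic pressure `u^2 = v^2 + U_f^2` (see [max_lift_flapping()]).
#' When gliding the thrust term is absent and `u^2 = v^2`. Thrust falls to
#' zero as the lift demand approaches the stall limit and is cut by the
#' torque coefficient above `v_thresh`.
#'
#' @param c_l Wingbeat-averaged lift coefficient, `|c_l| <= c_l_max`.
#' @param wing A [wing_config()] (carries span, area, mode).
#' @param v Airspeed (m s^-1).
#' @inheritParams friction_drag_coeff
#' @return Net thrust minus drag (N); negative values are net drag.
#' @export
thrust_minus_drag <- function(c_l, wing, v, morph,
                              consts = flight_constants()) {
  if (v <= 0) stop("airspeed must be positive", call. = FALSE)
  if (abs(c_l) > morph$c_l_max + 1e-12)
    stop("|c_l| exceeds c_l_max", call. = FALSE)
  c_d_fric <- friction_drag_coeff(v, wing, morph, consts)
  parasite <- (morph$c_d_body * morph$S_b + c_d_fric * wing$S_w) *
    0.5 * consts$rho * v^2
  u2 <- v^2 + if (wing$flapping) flap_speed_sq(morph) else 0
  induced <- if (wing$S_w > 0)
    c_l^2 * wing$S_w * consts$rho * u2 / (2 * pi * wing$AR) else 0
  thrust <- if (wing$flapping) {
    (1 - c_l^2 / morph$c_l_max^2) * pi^3 / 16 * consts$rho * wing$b^2 *
      sin(morph$theta / 2)^2 * morph$f^2 * morph$l_w^2 *
      c_torque(v, morph$v_thresh)
  } else 0
  thrust - parasite - induced
}

#' Drag-minimizing wing span for a gliding lift demand
#'
#' Closed-form optimum of net thrust-minus-drag over span, subject to
#' producing lift `L_star`: the friction drag of exposed wing area trades
#' against induced drag, giving
#' `b* = ((b_max - b_min) 8 L*^2 / (pi c_d_fric S_w_max (rho v^2)^2))^(1/3)`,
#' followed by the truncation cascade: clip to `[b_min, b_max]` and to the
#' muscle-torque bound `b <= b_min + L0 (b_max - b_min) / L*` (the same
#' moment-arm convention that defines the maximum-lift envelope of
#' [max_lift_gliding()], so every demand below that envelope is
#' achievable); if the implied lift coefficient exceeds `c_l_max`, the
#' span is recomputed from the stall limit
#' (`b = 2 L (b_max - b_min) / (S_w_max c_l_max rho v^2) + b_min`) and
#' re-clipped. Infeasible demands saturate at the lift-maximizing span.
#'
#' The friction coefficient entering the optimization is held fixed at the
#' species value (or, in Blasius mode, at its full-span value for this
#' airspeed); its weak span dependence is ignored in the optimum, exactly
#' as in the objective used by [resolve_forces()].
#'
#' @param L_star Desired lift (N), non-negative.
#' @inheritParams friction_drag_coeff
#' @return A list with `b` (m), `c_l`, `L` (achievable lift at that span),
#'   and `saturated` (TRUE when `L_star` is not attainable at any span).
#' @export
optimal_glide_span <- function(L_star, v, morph,
                               consts = flight_constants()) {
  if (v <= 0) stop("airspeed must be positive", call. = FALSE)
  if (L_star < 0) stop("L_star must be non-negative", call. = FALSE)
  ml <- max_lift_gliding(v, morph, consts)
  if (L_star > ml$L_max)
    return(list(b = ml$b_ml, c_l = morph$c_l_max, L = ml$L_max,
                saturated = TRUE))
  c_d_fric <- glide_fric_const(v, morph, consts)
  rv2 <- consts$rho * v^2
  b <- ((morph$b_max - morph$b_min) * 8 * L_star^2 /
          (pi * c_d_fric * morph$S_w_max * rv2^2))^(1 / 3)
  upper <- if (L_star > 0)
    morph$b_min + morph$L0 * (morph$b_max - morph$b_min) / L_star
  else morph$b_max
  b <- max(morph$b_min, min(b, morph$b_max, upper))
  S_w <- morph$S_w_max * (b - morph$b_min) / (morph$b_max - morph$b_min)
  c_l <- if (S_w > 0) 2 * L_star / (S_w * rv2) else
    if (L_star > 0) Inf else 0
  if (c_l > morph$c_l_max) {
    b <- 2 * L_star * (morph$b_max - morph$b_min) /
      (morph$S_w_max * morph$c_l_max * rv2) + morph$b_min
    b <- max(morph$b_min, min(b, morph$b_max, upper))
    S_w <- morph$S_w_max * (b - morph$b_min) / (morph$b_max - morph$b_min)
    c_l <- if (S_w > 0) 2 * L_star / (S_w * rv2) else 0
  }
  list(b = b, c_l = min(c_l, morph$c_l_max), L = L_star, saturated = FALSE)
}

# friction coefficient used inside the glide-span optimization: constant
# w.r.t. span (full-span chord in blasius mode)
glide_fric_const <- function(v, morph, consts) {
  if (morph$friction == "fixed") morph$c_d_fric_ref
  else friction_drag_coeff(v, wing_config(morph, morph$b_max), morph, consts,
                           mode = "blasius")
}

#' Resolve a lift demand into an achievable flight mode and forces
#'
#' Evaluates both flight modes — flapping (full span, maximum wingbeat
#' frequency) and gliding (drag-optimal retraction) — capping the demand at
#' each mode's maximum attainable lift, and selects the mode that meets the
#' demand most closely; among modes equally close, the one with the larger
#' net thrust wins, with ties going to the glide. When the demand exceeds
#' both maxima the bird simply exerts its largest attainable lift and the
#' result is flagged `saturated`.
#'
#' A non-zero control error `chi` perturbs the achieved lift
#' multiplicatively by `(1 + chi * |dc_l/dt| * e)` with `e ~ U(-1, 1)`,
#' modelling imprecision proportional to how fast the lift coefficient is
#' being changed; the baseline `chi = 0` is deterministic.
#'
#' @param L_desired Demanded lift magnitude (N), non-negative.
#' @inheritParams friction_drag_coeff
#' @param chi Control error parameter (dimensionless), default 0.
#' @param dcl_dt Current rate of change of the lift coefficient (s^-1),
#'   used only when `chi > 0`.
#' @return A list of class `force_resolution`: `L`, `TD`, `c_l`, `wing`
#'   (a [wing_config()]), `saturated`.
#' @export
resolve_forces <- function(L_desired, v, morph, consts = flight_constants(),
                           chi = 0, dcl_dt = 0) {
  if (L_desired < 0) stop("L_desired must be non-negative", call. = FALSE)
  # flapping candidate
  Lf <- min(L_desired, max_lift_flapping(v, morph, consts))
  wing_f <- wing_config(morph, morph$b_max, flapping = TRUE)
  clf <- 2 * Lf / (morph$S_w_max * consts$rho * (v^2 + flap_speed_sq(morph)))
  TDf <- thrust_minus_drag(clf, wing_f, v, morph, consts)
  # gliding candidate
  gl <- optimal_glide_span(L_desired, v, morph, consts)
  wing_g <- wing_config(morph, gl$b, flapping = FALSE)
  TDg <- thrust_minus_drag(gl$c_l, wing_g, v, morph, consts)
  miss_f <- L_desired - Lf
  miss_g <- L_desired - gl$L
  use_glide <- if (abs(miss_f - miss_g) > 1e-9 * (1 + L_desired))
    miss_g < miss_f else TDg >= TDf
  out <- if (use_glide)
    list(L = gl$L, TD = TDg, c_l = gl$c_l, wing = wing_g,
         saturated = gl$saturated)
  else
    list(L = Lf, TD = TDf, c_l = clf, wing = wing_f,
         saturated = miss_f > 1e-9 * (1 + L_desired))
  if (chi > 0) {
    err <- 1 + chi * abs(dcl_dt) * stats::runif(1, -1, 1)
    out$L <- min(max(out$L * err, 0),
                 max(max_lift_flapping(v, morph, consts),
                     max_lift_gliding(v, morph, consts)$L_max))
  }
  class(out) <- "force_resolution"
  out
}

#' Maximum roll acceleration
#'
#' Roll torque comes from antisymmetric lift on the two wings, each acting
#' at a quarter span: `M = L_max(b) b / 4` when the wings carry the largest
#' attainable differential lift. The span that maximizes lift also
#' maximizes roll acceleration (shrinking span cuts torque by the square of
#' retraction while inertia falls more slowly), so the roll-optimal span
#' equals the lift-maximizing span of [max_lift_gliding()]. The inertia is
#' [total_roll_inertia()] at retraction `phi = b / b_max`.
#'
#' @inheritParams friction_drag_coeff
#' @return A list with `omega_dot_max` (rad s^-2), `b` (span used, m),
#'   `M` (torque, N m), `I` (inertia, kg m^2).
#' @export
max_roll_acceleration <- function(v, morph, consts = flight_constants()) {
  ml <- max_lift_gliding(v, morph, consts)
  M <- ml$L_max * ml$b_ml / 4
  I <- total_roll_inertia(morph, ml$b_ml / morph$b_max)
  list(omega_dot_max = M / I, b = ml$b_ml, M = M, I = I)
}
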
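#' Physical constants of the flight medium
#'
#' Air density, gravitational acceleration and dynamic viscosity used
#' throughout the aerodynamic model. Defaults are standard sea-level values;
#' all are overridable (e.g. for altitude or temperature studies).
#'
#' @param rho Air density (kg m^-3).
#' @param g Gravitational acceleration (m s^-2).
#' @param mu_air Dynamic viscosity of air (Pa s), used for Reynolds-number
#'   dependent wing friction drag.
#' @return An object of class `flight_constants` (a named list).
#' @examples
#' flight_constants()
#' @export
flight_constants <- function(rho = 1.225, g = 9.81, mu_air = 1.81e-5) {
  stopifnot(rho > 0, g > 0, mu_air > 0)
  structure(list(rho = rho, g = g, mu_air = mu_air),
            class = "flight_constants")
}

#' @export
print.flight_constants <- function(x, ...) {
  cat("<flight_constants> rho =", x$rho, "kg/m^3, g =", x$g,
      "m/s^2, mu_air =", x$mu_air, "Pa s\n")
  invisible(x)
}

#' Species flight morphology
#'
#' Builds the vector of per-species physical parameters that drives the
#' wingbeat-averaged aerodynamic model: wingbeat frequency and amplitude,
#' wing geometry, masses, roll inertias, drag coefficients and physiological
#' limits. Derived quantities are filled in automatically:
#' total mass `m_total = m_b + 2 m_w` (a single bird has two wings),
#' the maximum lift at full span `L0 = 1.7 m_total g` (allometric torque
#' limit on the flight musculature), and a default minimum span
#' `b_min = 0.2 b_max` (fully tucked wings).
#'
#' Roll inertias default to allometric estimates ([body_roll_inertia()])
#' when not supplied; measured values always take precedence.
#'
#' @param species Species label (free text).
#' @param f Maximum wingbeat frequency (Hz).
#' @param l_w Wing length (m).
#' @param b_max Maximum wing span (m).
#' @param m_b Body mass (kg).
#' @param m_w Mass of a single wing (kg).
#' @param S_w_max Wing area at full span, both wings (m^2).
#' @param AR_max Aspect ratio at full span (`b_max^2 / S_w_max`).
#' @param theta Angular flapping amplitude, highest to lowest wing position
#'   (rad).
#' @param S_b Frontally projected body area (m^2).
#' @param c_d_body Body drag coefficient (referenced to `S_b`).
#' @param c_d_fric_ref Reference wing friction drag coefficient, used when
#'   `friction = "fixed"` and as the degenerate-wing fallback.
#' @param v_thresh Airspeed above which muscle torque limits flapping
#'   thrust (m s^-1).
#' @param c_l_max Maximum steady (wingbeat-averaged) lift coefficient.
#' @param b_min Minimum wing span (m); defaults to `0.2 * b_max`.
#' @param I_b Body roll inertia (kg m^2); allometric default.
#' @param I_wing Single-wing inertia about the shoulder (kg m^2).
#' @param J Wing mass-moment sum, `sum(m_i r_i)` over spanwise blade
#'   elements (kg m).
#' @param mass_convention `"total"` uses `m_b + 2 m_w` as the flying mass,
#'   `"body"` uses `m_b` alone.
#' @param friction Wing friction drag mode: `"fixed"` uses `c_d_fric_ref`,
#'   `"blasius"` uses the laminar flat-plate law at the current Reynolds
#'   number.
#' @return An object of class `bird_morphology` (a named list).
#' @seealso [falcon_morphology()], [starling_morphology()],
#'   [read_species_config()]
#' @export
bird_morphology <- function(species, f, l_w, b_max, m_b, m_w, S_w_max,
                            AR_max, theta, S_b, c_d_body, c_d_fric_ref,
                            v_thresh, c_l_max,
                            b_min = 0.2 * b_max,
                            I_b = NULL, I_wing = NULL, J = NULL,
                            mass_convention = c("total", "body"),
                            friction = c("fixed", "blasius")) {
  mass_convention <- match.arg(mass_convention)
  friction <- match.arg(friction)
  num <- c(f = f, l_w = l_w, b_max = b_max, m_b = m_b, m_w = m_w,
           S_w_max = S_w_max, AR_max = AR_max, theta = theta, S_b = S_b,
           c_d_body = c_d_body, c_d_fric_ref = c_d_fric_ref,
           v_thresh = v_thresh, c_l_max = c_l_max, b_min = b_min)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all morphological parameters must be finite and positive",
         call. = FALSE)
  if (b_min >= b_max) stop("b_min must be smaller than b_max", call. = FALSE)
  if (is.null(I_b)) I_b <- body_roll_inertia(m_b)
  if (is.null(I_wing) || is.null(J))
    stop("I_wing and J must be supplied (no allometric fallback exists)",
         call. = FALSE)
  stopifnot(I_b > 0, I_wing > 0, J > 0)
  m_total <- if (mass_convention == "total") m_b + 2 * m_w else m_b
  out <- list(species = species, f = f, l_w = l_w, b_max = b_max,
              b_min = b_min, m_b = m_b, m_w = m_w, I_b = I_b,
              I_wing = I_wing, J = J, S_w_max = S_w_max, AR_max = AR_max,
              theta = theta, S_b = S_b, c_d_body = c_d_body,
              c_d_fric_ref = c_d_fric_ref, v_thresh = v_thresh,
              c_l_max = c_l_max, mass_convention = mass_convention,
              friction = friction, m_total = m_total)
  out$L0 <- 1.7 * m_total * 9.81
  structure(out, class = "bird_morphology")
}

#' @export
print.bird_morphology <- function(x, ...) {
  cat("<bird_morphology>", x$species, "\n")
  cat(sprintf("  mass %.1f g (convention: %s), span %.3f m, wing area %.1f cm^2\n",
              1000 * x$m_total, x$mass_convention, x$b_max, 1e4 * x$S_w_max))
  cat(sprintf("  f_max %.1f Hz, theta %.3f rad, L0 %.2f N, v_thresh %.1f m/s\n",
              x$f, x$theta, x$L0, x$v_thresh))
  invisible(x)
}

#' Model peregrine falcon morphology
#'
#' Morphology of a male peregrine falcon (*Falco peregrinus*) assembled from
#' empirical measurements and allometric estimates. The wing friction drag
#' constant (9.35e-3) is calibrated jointly with the starling's so that the
#' model's maximum level speeds reproduce published estimates for the two
#' species (about 28 and 24 m s^-1); this ordering — the larger, faster bird
#' carrying the lower friction coefficient — is also what laminar
#' boundary-layer (Reynolds number) scaling requires.
#'
#' @param ... Overrides passed on to [bird_morphology()].
#' @return A `bird_morphology` object.
#' @examples
#' falcon_morphology()
#' @export
falcon_morphology <- function(...) {
  defaults <- list(species = "peregrine falcon", f = 5.1, l_w = 0.284,
                   b_max = 0.873, m_b = 528e-3, m_w = 32e-3,
                   I_b = 448.0e-6, I_wing = 296.6e-6, J = 2501.3e-6,
                   S_w_max = 89.7e-3, AR_max = 8.49, theta = 0.4 * pi,
                   S_b = 4.275e-3, c_d_body = 0.14, c_d_fric_ref = 9.35e-3,
                   v_thresh = 16.5, c_l_max = 1.6)
  do.call(bird_morphology, utils::modifyList(defaults, list(...)))
}

#' Model common starling morphology
#'
#' Morphology of a common starling (*Sturnus vulgaris*). See
#' [falcon_morphology()] for the calibration of the wing friction drag
#' constant (14e-3 here): the smaller, slower bird flies at lower Reynolds
#' number and therefore carries the larger laminar friction coefficient.
#'
#' @inheritParams falcon_morphology
#' @return A `bird_morphology` object.
#' @export
starling_morphology <- function(...) {
  defaults <- list(species = "common starling", f = 10.5, l_w = 0.185,
                   b_max = 0.39, m_b = 70e-3, m_w = 3.7e-3,
                   I_b = 15.65e-6, I_wing = 14.55e-6, J = 152.8e-6,
                   S_w_max = 24.14e-3, AR_max = 6.40, theta = 0.47 * pi,
                   S_b = 2.1e-3, c_d_body = 0.24, c_d_fric_ref = 14e-3,
                   v_thresh = 11.62, c_l_max = 1.6)
  do.call(bird_morphology, utils::modifyList(defaults, list(...)))
}

#' Allometric body roll inertia
#'
#' Scaling law for the roll-axis inertia of a bird body, calibrated to the
#' one species for which it has been measured directly (a 0.293 kg cockatoo
#' with I_b = 1.6855e-4 kg m^2). Body width scales as `0.098 m_b^0.35`, so
#' inertia scales as `I_b0 * 0.098^2 * m_b^1.70` with `I_b0 = 0.1346717`.
#' Used only as a fallback when a measured inertia is unavailable.
#'
#' @param m_b Body mass (kg), non-negative.
#' @return Roll inertia of the body (kg m^2).
#' @export
body_roll_inertia <- function(m_b) {
  if (!is.numeric(m_b) || any(!is.finite(m_b)) || any(m_b < 0))
    stop("m_b must be a non-negative finite number", call. = FALSE)
  0.1346717 * 0.098^2 * m_b^1.70
}

#' Wing roll inertia about the bird's centre of mass
#'
#' Parallel-axis transfer of the single-wing shoulder inertia to the bird's
#' centre of mass, at a given wing retraction. The shoulder sits half a
#' body width (`0.098 m_b^0.35 / 2`) from the centre line. With retraction
#' fraction `phi` (1 = fully extended) the shoulder inertia scales as
#' `phi^2` and the cross term as `phi`.
#'
#' @param morph A [bird_morphology()] object.
#' @param phi Retraction fraction in `[0, 1]` (current span / full span).
#' @return Inertia of one wing about the roll axis through the centre of
#'   mass (kg m^2).
#' @export
wing_inertia_about_cg <- function(morph, phi) {
  stopifnot(inherits(morph, "bird_morphology"))
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("phi must lie in [0, 1]", call. = FALSE)
  morph$I_wing * phi^2 +
    0.25 * 0.098^2 * morph$m_b^0.70 * morph$m_w +
    0.098 * morph$m_b^0.35 * morph$J * phi
}

#' Total roll moment of inertia
#'
#' Body inertia plus twice the single-wing inertia about the centre of mass
#' (wings are retracted symmetrically, so the centre of mass does not move).
#'
#' @inheritParams wing_inertia_about_cg
#' @return Total roll inertia (kg m^2).
#' @export
total_roll_inertia <- function(morph, phi) {
  morph$I_b + 2 * wing_inertia_about_cg(morph, phi)
}

#' Read / write a species configuration file
#'
#' Species morphology is serialized as YAML with field names matching
#' [bird_morphology()] arguments. Values round-trip exactly (YAML stores
#' full double precision).
#'
#' @param path File path.
#' @return `read_species_config()` returns a `bird_morphology`;
#'   `write_species_config()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_species_config(falcon_morphology(), p)
#' identical(read_species_config(p)$L0, falcon_morphology()$L0)
#' @export
read_species_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(bird_morphology, cfg)
}

#' @param morph A `bird_morphology` object to serialize.
#' @rdname read_species_config
#' @export
write_species_config <- function(morph, path) {
  stopifnot(inherits(morph, "bird_morphology"))
  keep <- c("species", "f", "l_w", "b_max", "m_b", "m_w", "S_w_max",
            "AR_max", "theta", "S_b", "c_d_body", "c_d_fric_ref",
            "v_thresh", "c_l_max", "b_min", "I_b", "I_wing", "J",
            "mass_convention", "friction")
  yaml::write_yaml(morph[keep], path, precision = 17)
  invisible(path)
}
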
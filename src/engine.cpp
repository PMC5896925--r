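// Simulation engine: wingbeat-averaged aerodynamics, PPN guidance with
// sampled noisy vision, bang-bang roll control, velocity-Verlet kinematics.
// Mirrors the R-level module functions exactly; consistency is enforced by
// tests comparing the exported shims below against the R implementations.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double PI3_16 = M_PI * M_PI * M_PI / 16.0;

struct Consts { double rho, g, mu; };

struct Morph {
  double f, lw, bmax, bmin, mb, mw, Ib, Iwing, J, Swmax, ARmax, theta,
         Sb, cdbody, cdfric, vthresh, clmax, mtotal, L0;
  int friction;            // 0 fixed, 1 blasius
  double cap_load;         // upper bound on lift (N), Inf when inactive
  double cap_rollacc;      // upper bound on roll acceleration (rad/s^2)
  double flapU2;           // mean-square flapping speed (precomputed)
  double thrust0;          // flapping thrust prefactor (precomputed)
};

static Morph unpack_morph(const NumericVector& m) {
  Morph M;
  M.f = m[0]; M.lw = m[1]; M.bmax = m[2]; M.bmin = m[3]; M.mb = m[4];
  M.mw = m[5]; M.Ib = m[6]; M.Iwing = m[7]; M.J = m[8]; M.Swmax = m[9];
  M.ARmax = m[10]; M.theta = m[11]; M.Sb = m[12]; M.cdbody = m[13];
  M.cdfric = m[14]; M.vthresh = m[15]; M.clmax = m[16]; M.mtotal = m[17];
  M.L0 = m[18]; M.friction = (int) m[19];
  M.cap_load = m[20]; M.cap_rollacc = m[21];
  double s = sin(0.5 * M.theta);
  M.flapU2 = 0.5 * std::pow(M_PI * M.f * s * M.lw, 2);
  M.thrust0 = PI3_16 * M.bmax * M.bmax * s * s * M.f * M.f * M.lw * M.lw;
  return M;
}

static Consts unpack_consts(const NumericVector& c) {
  Consts C; C.rho = c[0]; C.g = c[1]; C.mu = c[2]; return C;
}

static inline double sw_of_b(const Morph& M, double b) {
  return M.Swmax * (b - M.bmin) / (M.bmax - M.bmin);
}
static inline double ctorque(const Morph& M, double v) {
  return std::min(1.0, M.vthresh / v);
}
static inline double fric_coeff(const Morph& M, const Consts& C, double v,
                                double Sw, double b) {
  if (M.friction == 0 || Sw <= 0) return M.cdfric;
  double Re = C.rho * v * (Sw / b) / C.mu;
  return 2.0 * 1.328 / std::sqrt(Re);
}

// maximum gliding lift and the span achieving it (Lmax capped by cap_load)
static void max_lift_glide(const Morph& M, const Consts& C, double v,
                           double& Lmax, double& bml) {
  double qmax = 0.5 * C.rho * M.Swmax * M.clmax * v * v;
  bml = (M.bmax - M.bmin) * std::sqrt(M.L0 / qmax) + M.bmin;
  bool hi = bml >= M.bmax;
  bml = std::min(std::max(bml, M.bmin), M.bmax);
  Lmax = 0.5 * C.rho * sw_of_b(M, bml) * M.clmax * v * v;
  if (hi) Lmax = std::min(M.L0, Lmax);
  Lmax = std::min(Lmax, M.cap_load);
}

static inline double max_lift_flap(const Morph& M, const Consts& C,
                                   double v) {
  double stall = 0.5 * C.rho * M.Swmax * M.clmax * (v * v + M.flapU2);
  return std::min(std::min(M.L0, stall), M.cap_load);
}

// thrust minus drag at lift coefficient cl on a wing of span b
static double td_force(const Morph& M, const Consts& C, double cl, double b,
                       bool flapping, double v) {
  double Sw = sw_of_b(M, b);
  double cdf = fric_coeff(M, C, v, Sw, b);
  double parasite = (M.cdbody * M.Sb + cdf * Sw) * 0.5 * C.rho * v * v;
  double u2 = v * v + (flapping ? M.flapU2 : 0.0);
  double induced = 0.0;
  if (Sw > 0) {
    double AR = b * b / Sw;
    induced = cl * cl * Sw * C.rho * u2 / (2.0 * M_PI * AR);
  }
  double thrust = 0.0;
  if (flapping)
    thrust = (1.0 - cl * cl / (M.clmax * M.clmax)) * C.rho * M.thrust0 *
             ctorque(M, v);
  return thrust - parasite - induced;
}

// drag-optimal glide span for lift demand Lstar (with truncation cascade)
static void glide_opt(const Morph& M, const Consts& C, double Lstar,
                      double v, double& b, double& cl, double& L,
                      bool& sat) {
  double Lmax, bml;
  max_lift_glide(M, C, v, Lmax, bml);
  if (Lstar > Lmax) { b = bml; cl = M.clmax; L = Lmax; sat = true; return; }
  sat = false; L = Lstar;
  double cdf = (M.friction == 0) ? M.cdfric
    : fric_coeff(M, C, v, M.Swmax, M.bmax);
  double rv2 = C.rho * v * v;
  b = std::cbrt((M.bmax - M.bmin) * 8.0 * Lstar * Lstar /
                (M_PI * cdf * M.Swmax * rv2 * rv2));
  double upper = (Lstar > 0) ?
    M.bmin + M.L0 * (M.bmax - M.bmin) / Lstar : M.bmax;
  b = std::max(M.bmin, std::min(std::min(b, M.bmax), upper));
  double Sw = sw_of_b(M, b);
  cl = (Sw > 0) ? 2.0 * Lstar / (Sw * rv2) : (Lstar > 0 ? INFINITY : 0.0);
  if (cl > M.clmax) {
    b = 2.0 * Lstar * (M.bmax - M.bmin) / (M.Swmax * M.clmax * rv2) + M.bmin;
    b = std::max(M.bmin, std::min(std::min(b, M.bmax), upper));
    Sw = sw_of_b(M, b);
    cl = (Sw > 0) ? 2.0 * Lstar / (Sw * rv2) : 0.0;
  }
  if (cl > M.clmax) cl = M.clmax;
}

struct Resolution { double L, TD, cl, b; bool flapping, saturated; };

// choose flap vs glide: meet the demand most closely, break ties by TD,
// remaining ties go to the glide
static Resolution resolve(const Morph& M, const Consts& C, double Ldes,
                          double v) {
  double Lf = std::min(Ldes, max_lift_flap(M, C, v));
  double clf = 2.0 * Lf / (M.Swmax * C.rho * (v * v + M.flapU2));
  double TDf = td_force(M, C, clf, M.bmax, true, v);
  double bg, clg, Lg; bool satg;
  glide_opt(M, C, Ldes, v, bg, clg, Lg, satg);
  double TDg = td_force(M, C, clg, bg, false, v);
  double miss_f = Ldes - Lf, miss_g = Ldes - Lg;
  double tol = 1e-9 * (1.0 + Ldes);
  bool use_glide = (std::fabs(miss_f - miss_g) > tol) ? (miss_g < miss_f)
                                                      : (TDg >= TDf);
  Resolution R;
  if (use_glide) { R.L = Lg; R.TD = TDg; R.cl = clg; R.b = bg;
                   R.flapping = false; R.saturated = satg; }
  else { R.L = Lf; R.TD = TDf; R.cl = clf; R.b = M.bmax;
         R.flapping = true; R.saturated = miss_f > tol; }
  return R;
}

// maximal roll acceleration at current airspeed (at the max-lift span)
static double roll_max(const Morph& M, const Consts& C, double v,
                       double& b_roll, double& I_roll) {
  double Lmax, bml;
  max_lift_glide(M, C, v, Lmax, bml);
  double Mx = Lmax * bml / 4.0;
  double phi = bml / M.bmax;
  I_roll = M.Ib + 2.0 * (M.Iwing * phi * phi +
           0.25 * 0.098 * 0.098 * std::pow(M.mb, 0.70) * M.mw +
           0.098 * std::pow(M.mb, 0.35) * M.J * phi);
  b_roll = bml;
  return std::min(Mx / I_roll, M.cap_rollacc);
}

// ---------------------------------------------------------------------------
// state and per-step control

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x+o.x, y+o.y, z+o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x-o.x, y-o.y, z-o.z); }
  Vec3 operator*(double s) const { return Vec3(x*s, y*s, z*s); }
  double dot(const Vec3& o) const { return x*o.x + y*o.y + z*o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y*o.z - z*o.y, z*o.x - x*o.z, x*o.y - y*o.x);
  }
  double norm() const { return std::sqrt(x*x + y*y + z*z); }
};

struct Bird {
  Vec3 r, v, a;
  double Omega, omega;
  Vec3 ex, ey, ez;       // body axes
  Vec3 ey_prev;
  double cl_prev;        // for the control-error term
  double load, rollacc;  // diagnostics of the last step
};

static void update_axes(Bird& B) {
  B.ex = B.v * (1.0 / B.v.norm());
  Vec3 up(0, 0, 1);
  Vec3 ey0 = up.cross(B.ex);
  double n = ey0.norm();
  if (n < 1e-9) {
    ey0 = B.ey_prev - B.ex * B.ey_prev.dot(B.ex);
    n = ey0.norm();
    if (n < 1e-9) ey0 = Vec3(0, 1, 0); else ey0 = ey0 * (1.0 / n);
  } else ey0 = ey0 * (1.0 / n);
  Vec3 ez0 = B.ex.cross(ey0);
  double cO = std::cos(B.Omega), sO = std::sin(B.Omega);
  B.ey = ey0 * cO + ez0 * sO;
  B.ez = ez0 * cO - ey0 * sO;
  B.ey_prev = B.ey;
}

// apply guidance command a_star: weight support, lift resolution, roll
// control, then one Verlet + Euler step. chi > 0 adds control error.
static void control_and_step(Bird& B, const Morph& M, const Consts& C,
                             const Vec3& a_star, double chi, double dt,
                             bool strict_sign) {
  double v = B.v.norm();
  Vec3 a_steer = strict_sign ? a_star - Vec3(0, 0, C.g)
                             : a_star + Vec3(0, 0, C.g);
  double ay = a_steer.dot(B.ey), az = a_steer.dot(B.ez);
  double mag = std::sqrt(ay * ay + az * az);
  double Lstar = M.mtotal * mag;
  Resolution R = resolve(M, C, Lstar, v);
  double L = R.L, TD = R.TD;
  if (chi > 0) {
    double dcl = std::fabs(R.cl - B.cl_prev) / dt;
    double err = 1.0 + chi * dcl * R::runif(-1.0, 1.0);
    double Lmax, bml; max_lift_glide(M, C, v, Lmax, bml);
    double cap = std::max(Lmax, max_lift_flap(M, C, v));
    L = std::min(std::max(L * err, 0.0), cap);
  }
  B.cl_prev = R.cl;
  B.load = L / (M.mtotal * C.g);
  // roll control toward the demand direction: the signed roll that aligns
  // e_z' with the demand is -atan2(ay, az) under the right-handed axis
  // convention (rolling by +Omega carries body coordinates the other way)
  double gamma = (mag > 0) ? -std::atan2(ay, az) : 0.0;
  double b_roll, I_roll;
  double omdot_max = roll_max(M, C, v, b_roll, I_roll);
  // proximate time-optimal roll servo: outside a small linear zone the
  // exact bang-bang switching rule applies (accelerate toward gamma
  // unless omega has the sign of gamma and omega^2 > 2 omdot_max |gamma|,
  // in which case brake); inside the zone a critically damped linear law
  // takes over, so a slowly moving bank target is tracked without the
  // discretization chatter of a pure switching law
  const double gamma_lin = 0.02;
  double omdot;
  if (std::fabs(gamma) > gamma_lin) {
    double s = (gamma > 0) ? 1.0 : -1.0;
    bool brake = (B.omega * s > 0) &&
                 (B.omega * B.omega > 2.0 * omdot_max * std::fabs(gamma));
    omdot = (brake ? -s : s) * omdot_max;
  } else {
    // gain capped so the discrete linear loop stays well inside stability
    // at coarse integration steps
    double kp = std::min(omdot_max / gamma_lin,
                         0.04 / (dt * dt));
    double kd = 2.0 * std::sqrt(kp);
    omdot = kp * gamma - kd * B.omega;
    omdot = std::max(-omdot_max, std::min(omdot_max, omdot));
  }
  B.rollacc = omdot;
  // forces and translation (velocity Verlet; force held over the step)
  Vec3 F = B.ex * TD + B.ez * L - Vec3(0, 0, M.mtotal * C.g);
  Vec3 a_new = F * (1.0 / M.mtotal);
  B.r = B.r + B.v * dt + B.a * (0.5 * dt * dt);
  B.v = B.v + (B.a + a_new) * (0.5 * dt);
  B.a = a_new;
  // roll kinematics (explicit Euler, angle first)
  B.Omega += B.omega * dt;
  B.omega += omdot * dt;
  if (B.Omega > M_PI) B.Omega -= 2.0 * M_PI;
  if (B.Omega < -M_PI) B.Omega += 2.0 * M_PI;
  update_axes(B);
}

// visual measurement of the line of sight with bounded angular error
static Vec3 measure(const Vec3& rd, double xi, int err_mode) {
  double range = rd.norm();
  if (xi <= 0) return rd;
  Vec3 rhat = rd * (1.0 / range);
  Vec3 ref = (std::fabs(rhat.x) < 0.9) ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
  Vec3 u1 = rhat.cross(ref); u1 = u1 * (1.0 / u1.norm());
  Vec3 u2 = rhat.cross(u1);
  double psi = R::runif(0.0, 2.0 * M_PI);
  double mag;
  if (err_mode == 1) {
    double cosang = R::runif(std::cos(xi), 1.0);
    mag = std::tan(std::acos(cosang));
  } else {
    mag = R::runif(0.0, xi);
  }
  Vec3 eps = (u1 * std::cos(psi) + u2 * std::sin(psi)) * mag;
  return rd + eps * range;
}

static Vec3 random_unit_sphere() {
  double z = R::runif(-1.0, 1.0);
  double az = R::runif(0.0, 2.0 * M_PI);
  double c = std::sqrt(std::max(0.0, 1.0 - z * z));
  return Vec3(c * std::cos(az), c * std::sin(az), z);
}

static double prey_amax(const Morph& M, const Consts& C, double v) {
  double Lg, bml; max_lift_glide(M, C, v, Lg, bml);
  return std::max(Lg, max_lift_flap(M, C, v)) / M.mtotal;
}

// prey forcing command (mode 0 straight, 1 smooth, 2 nonsmooth)
static Vec3 prey_command(const Bird& P, const NumericVector& pp, double t,
                         double z0, const Morph& M, const Consts& C,
                         const Vec3& target_dir, Vec3& q, double dt,
                         double c5_ref_dt) {
  int mode = (int) pp[0];
  double v = P.v.norm();
  double amax = prey_amax(M, C, v);
  double kappa = z0 - P.r.z;
  if (mode == 0) {
    Vec3 vhat = P.v * (1.0 / v);
    Vec3 perp = target_dir - vhat * target_dir.dot(vhat);
    double np = perp.norm();
    if (np < 1e-12) return Vec3(0, 0, 0);
    Vec3 u = perp * (1.0 / np);
    double ang = std::asin(std::min(1.0, np));
    if (target_dir.dot(vhat) < 0) ang = M_PI - ang;
    double disc = C.g * u.z * C.g * u.z + amax * amax - C.g * C.g;
    double s_cap = (disc <= 0) ? 0.0 : -C.g * u.z + std::sqrt(disc);
    return u * (s_cap * std::min(1.0, ang / 0.1));
  }
  if (mode == 1) {
    Vec3 h = P.ex.cross(Vec3(0, 0, 1));
    double nh = h.norm();
    h = (nh < 1e-9) ? P.ey_prev : h * (1.0 / nh);
    double lat = std::pow(pp[1] * std::sin(pp[2] * t) + pp[1], pp[3]) * amax;
    return h * lat + Vec3(0, 0, pp[4] * kappa);
  }
  // nonsmooth: random-walk direction, switching rate invariant to dt
  double p_switch = std::min(1.0, pp[5] * dt / c5_ref_dt);
  if (R::runif(0.0, 1.0) < p_switch) {
    double el = R::runif(-pp[9], pp[9]) * M_PI / 180.0;
    double az = R::runif(0.0, 2.0 * M_PI);
    Vec3 Q(std::cos(el) * std::cos(az), std::cos(el) * std::sin(az),
           std::sin(el));
    Vec3 qn = q * pp[8] + Q * (1.0 - pp[8]);
    q = qn * (1.0 / qn.norm());
  }
  return q * (pp[6] * amax) + Vec3(0, 0, pp[7] * kappa);
}

static void init_bird(Bird& B, const Vec3& r, const Vec3& v) {
  B.r = r; B.v = v; B.a = Vec3(0, 0, 0);
  B.Omega = 0; B.omega = 0;
  B.ey_prev = Vec3(0, 1, 0);
  B.cl_prev = 0; B.load = 0; B.rollacc = 0;
  update_axes(B);
}

static void check_finite(const Bird& B, double t, const char* who) {
  if (!std::isfinite(B.r.x + B.r.y + B.r.z + B.v.x + B.v.y + B.v.z +
                     B.Omega + B.omega))
    stop("numerical blow-up in %s state at t = %f "
         "(r = [%f, %f, %f], |v| = %f)", who, t, B.r.x, B.r.y, B.r.z,
         B.v.norm());
}

// ---------------------------------------------------------------------------
// exported: single engagement

// [[Rcpp::export]]
List cpp_run_engagement(NumericVector falcon_morph,
                        NumericVector prey_morph,
                        NumericVector consts,
                        NumericVector prey_pars,
                        NumericVector config) {
  Morph MF = unpack_morph(falcon_morph);
  Morph MP = unpack_morph(prey_morph);
  Consts C = unpack_consts(consts);
  double N = config[0], altitude = config[1], horiz = config[2];
  double tau = config[3], xi = config[4], chi = config[5], dt = config[6];
  double catch_r = config[7], miss_r = config[8], blind = config[9];
  double timeout = config[10], v0p = config[11], v0f = config[12];
  int stride = (int) config[13];
  bool strict_sign = config[14] != 0;
  int err_mode = (int) config[15];
  double c5_ref_dt = config[16];
  double cos_blind = std::cos(blind);

  Bird P, F;
  init_bird(P, Vec3(0, 0, 0), random_unit_sphere() * v0p);
  Vec3 fpos(horiz, 0, altitude);
  Vec3 fdir = (Vec3(0, 0, 0) - fpos);
  double fr = fdir.norm();
  if (fr < 1e-12) fdir = Vec3(-1, 0, 0); else fdir = fdir * (1.0 / fr);
  init_bird(F, fpos, fdir * v0f);

  // straight-mode target heading: random azimuth, elevation within 2.5 deg
  double az0 = R::runif(0.0, 2.0 * M_PI);
  double el0 = R::runif(-2.5, 2.5) * M_PI / 180.0;
  Vec3 target_dir(std::cos(el0) * std::cos(az0),
                  std::cos(el0) * std::sin(az0), std::sin(el0));
  // nonsmooth initial direction
  double elq = R::runif(-prey_pars[9], prey_pars[9]) * M_PI / 180.0;
  double azq = R::runif(0.0, 2.0 * M_PI);
  Vec3 q(std::cos(elq) * std::cos(azq), std::cos(elq) * std::sin(azq),
         std::sin(elq));

  long n_steps = (long) std::ceil(timeout / dt);
  long cap = n_steps / stride + 2;
  NumericMatrix log(cap, 15);
  long logged = 0;

  Vec3 rhat_prev; bool have_prev = false;
  Vec3 lambda_dot(0, 0, 0);
  double next_sample = 0.0;
  double z0 = 0.0;
  int outcome = 2;  // 0 catch, 1 near-miss, 2 timeout
  double t_end = timeout, intercept_speed = NA_REAL;
  double min_dist = (F.r - P.r).norm();
  bool armed = false;

  long step = 0;
  double t = 0.0;
  while (t < timeout) {
    Vec3 rd = P.r - F.r;           // falcon-to-prey
    double dist = rd.norm();
    if (dist < min_dist) min_dist = dist;
    if (dist <= catch_r) {
      outcome = 0; t_end = t; intercept_speed = F.v.norm(); break;
    }
    if (armed && dist > miss_r) {
      // prey behind the falcon, inside the blind cone: engagement lost
      Vec3 back = F.ex * (-1.0);
      if (back.dot(rd) / dist >= cos_blind) {
        outcome = 1; t_end = t; intercept_speed = F.v.norm(); break;
      }
    }
    if (dist < miss_r) armed = true;

    // vision: sample-and-hold every tau
    if (t >= next_sample - 0.5 * dt) {
      Vec3 rhat = measure(rd, xi, err_mode);
      if (have_prev) {
        Vec3 vhat = (rhat - rhat_prev) * (1.0 / tau);
        double d2 = rhat.dot(rhat);
        lambda_dot = rhat.cross(vhat) * (1.0 / d2);
      }
      rhat_prev = rhat; have_prev = true;
      next_sample += tau;
    }

    if (step % stride == 0 && logged < cap) {
      log(logged, 0) = t;           log(logged, 1) = dist;
      log(logged, 2) = F.v.norm();  log(logged, 3) = F.a.norm();
      log(logged, 4) = F.load;      log(logged, 5) = F.Omega;
      log(logged, 6) = P.v.norm();  log(logged, 7) = P.a.norm();
      log(logged, 8) = P.load;
      log(logged, 9) = F.r.x;  log(logged, 10) = F.r.y;
      log(logged, 11) = F.r.z;
      log(logged, 12) = P.r.x; log(logged, 13) = P.r.y;
      log(logged, 14) = P.r.z;
      logged++;
    }

    Vec3 a_star_p = prey_command(P, prey_pars, t, z0, MP, C, target_dir, q,
                                 dt, c5_ref_dt);
    Vec3 a_star_f = lambda_dot.cross(F.v) * N;
    control_and_step(P, MP, C, a_star_p, 0.0, dt, strict_sign);
    control_and_step(F, MF, C, a_star_f, chi, dt, strict_sign);
    step++; t = step * dt;
    if ((step & 1023) == 0) { check_finite(F, t, "falcon");
                              check_finite(P, t, "prey"); }
  }
  check_finite(F, t, "falcon"); check_finite(P, t, "prey");
  if (outcome == 2) { t_end = timeout; intercept_speed = F.v.norm(); }

  return List::create(
    _["outcome"] = outcome, _["t_end"] = t_end,
    _["intercept_speed"] = intercept_speed, _["min_distance"] = min_dist,
    _["trajectory"] = log(Range(0, std::max(logged - 1, (long) 0)), _),
    _["n_steps"] = (double) step);
}

// ---------------------------------------------------------------------------
// exported: prey-only run for forcing statistics

// [[Rcpp::export]]
List cpp_run_prey(NumericVector morph, NumericVector consts,
                  NumericVector prey_pars, double duration, double dt,
                  bool keep_commands, double c5_ref_dt = 1e-4,
                  double v0 = 11.0) {
  Morph M = unpack_morph(morph);
  Consts C = unpack_consts(consts);
  Bird P;
  init_bird(P, Vec3(0, 0, 0), random_unit_sphere() * v0);
  double az0 = R::runif(0.0, 2.0 * M_PI);
  double el0 = R::runif(-2.5, 2.5) * M_PI / 180.0;
  Vec3 target_dir(std::cos(el0) * std::cos(az0),
                  std::cos(el0) * std::sin(az0), std::sin(el0));
  double elq = R::runif(-prey_pars[9], prey_pars[9]) * M_PI / 180.0;
  double azq = R::runif(0.0, 2.0 * M_PI);
  Vec3 q(std::cos(elq) * std::cos(azq), std::cos(elq) * std::sin(azq),
         std::sin(elq));
  long n = (long) std::round(duration / dt);
  double sum_load = 0, sum_roll = 0, sum_speed = 0;
  double zmin = 0, zmax = 0;
  long cmd_stride = std::max((long) 1, (long) std::round(0.01 / dt));
  long cmd_cap = keep_commands ? n / cmd_stride + 2 : 1;
  NumericMatrix cmds(keep_commands ? cmd_cap : 1, 3);
  long ncmd = 0;
  for (long step = 0; step < n; step++) {
    double t = step * dt;
    Vec3 a_star = prey_command(P, prey_pars, t, 0.0, M, C, target_dir, q,
                               dt, c5_ref_dt);
    if (keep_commands && step % cmd_stride == 0 && ncmd < cmd_cap) {
      cmds(ncmd, 0) = a_star.x; cmds(ncmd, 1) = a_star.y;
      cmds(ncmd, 2) = a_star.z; ncmd++;
    }
    control_and_step(P, M, C, a_star, 0.0, dt, false);
    sum_load += P.load;
    sum_roll += std::fabs(P.rollacc);
    sum_speed += P.v.norm();
    if (P.r.z < zmin) zmin = P.r.z;
    if (P.r.z > zmax) zmax = P.r.z;
    if ((step & 8191) == 0) check_finite(P, t, "prey");
  }
  List out = List::create(
    _["mean_load_factor"] = sum_load / n,
    _["mean_abs_roll_accel"] = sum_roll / n,
    _["altitude_range"] = NumericVector::create(zmin, zmax),
    _["mean_speed"] = sum_speed / n,
    _["final_v"] = NumericVector::create(P.v.x, P.v.y, P.v.z),
    _["target_dir"] = NumericVector::create(target_dir.x, target_dir.y,
                                            target_dir.z));
  if (keep_commands)
    out["commands"] = cmds(Range(0, std::max(ncmd - 1, (long) 0)), _);
  return out;
}

// ---------------------------------------------------------------------------
// exported shims for consistency tests against the R implementations

// [[Rcpp::export]]
NumericVector cpp_resolve(NumericVector morph, NumericVector consts,
                          double L_desired, double v) {
  Morph M = unpack_morph(morph);
  Consts C = unpack_consts(consts);
  Resolution R = resolve(M, C, L_desired, v);
  return NumericVector::create(
    _["L"] = R.L, _["TD"] = R.TD, _["c_l"] = R.cl, _["b"] = R.b,
    _["flapping"] = R.flapping ? 1.0 : 0.0,
    _["saturated"] = R.saturated ? 1.0 : 0.0);
}

// [[Rcpp::export]]
NumericVector cpp_roll_max(NumericVector morph, NumericVector consts,
                           double v) {
  Morph M = unpack_morph(morph);
  Consts C = unpack_consts(consts);
  double b_roll, I_roll;
  double om = roll_max(M, C, v, b_roll, I_roll);
  return NumericVector::create(_["omega_dot_max"] = om, _["b"] = b_roll,
                               _["I"] = I_roll);
}
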
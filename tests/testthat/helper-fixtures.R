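# shared fixtures and independent oracles for the test suite

fal <- falcon_morphology()
sta <- starling_morphology()
csts <- flight_constants()

# independent thrust-minus-drag oracle, written directly from the force law
# with no calls into the package's aerodynamics functions
oracle_td <- function(L, b, v, m, flapping, c_d_fric = m$c_d_fric_ref,
                      cc = csts) {
  S <- m$S_w_max * (b - m$b_min) / (m$b_max - m$b_min)
  Uf2 <- if (flapping) 0.5 * (pi * m$f * sin(m$theta / 2) * m$l_w)^2 else 0
  cl <- if (S > 0) 2 * L / (S * cc$rho * (v^2 + Uf2)) else 0
  if (S <= 0 && L > 0) return(-Inf)   # demand unattainable with no wing
  parasite <- (m$c_d_body * m$S_b + c_d_fric * S) * 0.5 * cc$rho * v^2
  induced <- if (S > 0) cl^2 * S * cc$rho * (v^2 + Uf2) /
    (2 * pi * (b^2 / S)) else 0
  thrust <- if (flapping)
    (1 - cl^2 / m$c_l_max^2) * pi^3 / 16 * cc$rho * b^2 *
      sin(m$theta / 2)^2 * m$f^2 * m$l_w^2 * min(1, m$v_thresh / v)
  else 0
  if (S > 0 && cl > m$c_l_max) return(-Inf)  # stalled: infeasible
  thrust - parasite - induced
}

# grid-search oracle: best gliding span for a lift demand, maximizing TD
oracle_best_glide_span <- function(L, v, m, n_grid = 1e4, cc = csts) {
  bs <- seq(m$b_min, m$b_max, length.out = n_grid)
  # feasibility: stall and torque limits
  tds <- vapply(bs, function(b) {
    S <- m$S_w_max * (b - m$b_min) / (m$b_max - m$b_min)
    cl <- if (S > 0) 2 * L / (S * cc$rho * v^2) else Inf
    if (L > 0 && (cl > m$c_l_max ||
                  L * (b - m$b_min) > m$L0 * (m$b_max - m$b_min)))
      return(-Inf)
    oracle_td(L, b, v, m, flapping = FALSE, cc = cc)
  }, numeric(1))
  if (all(!is.finite(tds))) return(NULL)
  list(b = bs[which.max(tds)], td = max(tds))
}

# grid-search oracle: maximum gliding lift under stall + torque-arm limits
# (the torque-limited lift behind the closed-form optimum is
#  L0 (b_max - b_min) / (b - b_min))
oracle_max_glide_lift <- function(v, m, n_grid = 1e4, cc = csts) {
  bs <- seq(m$b_min + 1e-9, m$b_max, length.out = n_grid)
  Ls <- vapply(bs, function(b) {
    S <- m$S_w_max * (b - m$b_min) / (m$b_max - m$b_min)
    stall <- 0.5 * cc$rho * S * m$c_l_max * v^2
    torque <- m$L0 * (m$b_max - m$b_min) / (b - m$b_min)
    min(stall, torque)
  }, numeric(1))
  max(Ls)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

vcross_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
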
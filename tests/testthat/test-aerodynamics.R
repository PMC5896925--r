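test_that("torque coefficient caps at 1 and decays as v_thresh/v", {
  expect_equal(c_torque(0.5 * 16.5, 16.5), 1)
  expect_equal(c_torque(2 * 16.5, 16.5), 0.5)
  expect_equal(c_torque(16.5, 16.5), 1)
  eps <- 1e-9
  expect_equal(c_torque(16.5 + eps, 16.5), 1, tolerance = 1e-6)
  expect_error(c_torque(-1, 16.5), "positive")
})

test_that("Blasius friction coefficient scales as inverse sqrt Reynolds", {
  w <- wing_config(fal, fal$b_max)
  c1 <- friction_drag_coeff(5, w, fal, csts, mode = "blasius")
  c4 <- friction_drag_coeff(20, w, fal, csts, mode = "blasius")
  expect_equal(c4, c1 / 2, tolerance = 1e-12)  # 4x speed = 4x Re
  # low-speed full-span value is the same order as the species constant
  expect_gt(c1, 0.014 / 2)
  expect_lt(c1, 0.014 * 2)
  # fixed mode ignores speed
  expect_identical(friction_drag_coeff(5, w, fal, csts, mode = "fixed"),
                   friction_drag_coeff(50, w, fal, csts, mode = "fixed"))
  # degenerate wing falls back to the reference constant
  w0 <- wing_config(fal, fal$b_min)
  expect_identical(friction_drag_coeff(10, w0, fal, csts,
                                       mode = "blasius"),
                   fal$c_d_fric_ref)
})

test_that("gliding max lift: clipping, torque-arm identity and grid oracle", {
  # slow flight: span clips at full extension, stall (or L0) governs
  slow <- max_lift_gliding(3, sta, csts)
  expect_equal(slow$b_ml, sta$b_max)
  expect_equal(slow$L_max,
               min(sta$L0, 0.5 * csts$rho * sta$S_w_max * sta$c_l_max * 9))
  # unclipped optimum: stall lift there equals the torque-arm bound
  # L0 (b_max - b_min) / (b_ml - b_min) that the closed form encodes
  for (v in c(12, 20, 40)) {
    ml <- max_lift_gliding(v, fal, csts)
    expect_gt(ml$b_ml, fal$b_min); expect_lt(ml$b_ml, fal$b_max)
    torque_lift <- fal$L0 * (fal$b_max - fal$b_min) / (ml$b_ml - fal$b_min)
    expect_rel(ml$L_max, torque_lift, 1e-9)
  }
  # closed form matches the brute-force maximization to < 0.1%
  for (m in list(fal, sta)) for (v in c(8, 15, 30, 60)) {
    expect_rel(max_lift_gliding(v, m, csts)$L_max,
               oracle_max_glide_lift(v, m), 1e-3)
  }
})

test_that("thrust-minus-drag: structural limits and concavity in lift", {
  wf <- wing_config(fal, fal$b_max, flapping = TRUE)
  # at the stall-limit coefficient the flapping thrust term vanishes:
  # what remains is exactly parasite plus induced drag
  v <- 20
  td_stall <- thrust_minus_drag(fal$c_l_max, wf, v, fal, csts)
  expect_lt(td_stall, 0)
  u2 <- v^2 + 0.5 * (pi * fal$f * sin(fal$theta / 2) * fal$l_w)^2
  parasite <- (fal$c_d_body * fal$S_b + fal$c_d_fric_ref * fal$S_w_max) *
    0.5 * csts$rho * v^2
  induced <- fal$c_l_max^2 * fal$S_w_max * csts$rho * u2 /
    (2 * pi * fal$b_max^2 / fal$S_w_max)
  expect_equal(td_stall, -parasite - induced, tolerance = 1e-12)
  # gliding with fully retracted wings: body drag only
  w0 <- wing_config(fal, fal$b_min)
  expect_equal(thrust_minus_drag(0, w0, 30, fal, csts),
               -fal$c_d_body * fal$S_b * 0.5 * csts$rho * 30^2)
  expect_error(thrust_minus_drag(2, wf, 20, fal, csts), "c_l_max")
  # TD is concave (negative curvature) in L at fixed speed and mode
  v <- 18
  Uf2 <- 0.5 * (pi * fal$f * sin(fal$theta / 2) * fal$l_w)^2
  Ls <- seq(0, fal$L0, length.out = 30)
  tds <- vapply(Ls, function(L) {
    cl <- 2 * L / (fal$S_w_max * csts$rho * (v^2 + Uf2))
    thrust_minus_drag(cl, wf, v, fal, csts)
  }, numeric(1))
  expect_true(all(diff(diff(tds)) < 1e-9))
})

test_that("optimal glide span matches the brute-force search to < 0.1%", {
  expect_equal(optimal_glide_span(0, 20, fal, csts)$b, fal$b_min)
  for (m in list(fal, sta)) {
    for (v in c(10, 20, 45)) {
      for (frac in c(0.15, 0.4, 0.8)) {
        L <- frac * max_lift_gliding(v, m, csts)$L_max
        got <- optimal_glide_span(L, v, m, csts)
        ref <- oracle_best_glide_span(L, v, m)
        td_got <- oracle_td(L, got$b, v, m, flapping = FALSE)
        # achieved TD within 0.1% of the grid optimum (absolute floor for
        # near-zero TD)
        expect_lt(ref$td - td_got,
                  1e-3 * max(abs(ref$td), 1e-3))
      }
    }
  }
  # large demand at moderate speed: the muscle-torque bound governs the
  # span (same moment-arm convention as the max-lift envelope)
  v <- 25
  L <- 0.95 * max_lift_gliding(v, fal, csts)$L_max
  got <- optimal_glide_span(L, v, fal, csts)
  expect_lte(got$b,
             fal$b_min + fal$L0 * (fal$b_max - fal$b_min) / L + 1e-12)
  expect_lte(got$c_l, fal$c_l_max + 1e-12)
})

test_that("force resolution selects modes sensibly and reports saturation", {
  r1 <- resolve_forces(2, 20, sta, csts)
  r2 <- resolve_forces(2, 20, sta, csts)
  expect_identical(r1[c("L", "TD", "c_l")], r2[c("L", "TD", "c_l")])
  # infeasible demand saturates at the largest attainable lift
  big <- resolve_forces(100, 15, sta, csts)
  expect_true(big$saturated)
  expect_equal(big$L, max(max_lift_flapping(15, sta, csts),
                          max_lift_gliding(15, sta, csts)$L_max))
  # at high speed and modest demand the glide out-thrusts torque-crushed,
  # parasite-heavy flapping
  fast <- resolve_forces(0.3 * fal$m_total * 9.81, 80, fal, csts)
  expect_false(fast$wing$flapping)
  # achieved lift never exceeds either mode limit
  for (v in c(6, 12, 25, 60)) {
    r <- resolve_forces(3 * fal$m_total * 9.81, v, fal, csts)
    expect_lte(r$L, max(max_lift_flapping(v, fal, csts),
                        max_lift_gliding(v, fal, csts)$L_max) + 1e-12)
  }
})

test_that("roll acceleration is maximized at the max-lift span", {
  for (m in list(fal, sta)) for (v in c(8, 15, 30)) {
    got <- max_roll_acceleration(v, m, csts)
    # brute force over span: torque from stall/torque-limited lift at each
    # span, inertia at matching retraction
    bs <- seq(m$b_min + 1e-6, m$b_max, length.out = 2000)
    accs <- vapply(bs, function(b) {
      S <- m$S_w_max * (b - m$b_min) / (m$b_max - m$b_min)
      stall <- 0.5 * csts$rho * S * m$c_l_max * v^2
      torque_arm <- m$L0 * (m$b_max - m$b_min) / (b - m$b_min)
      L <- min(stall, torque_arm, if (b >= m$b_max - 1e-9) m$L0 else Inf)
      L * b / 4 / total_roll_inertia(m, b / m$b_max)
    }, numeric(1))
    expect_rel(got$omega_dot_max, max(accs), 5e-3)
    expect_rel(got$b, bs[which.max(accs)], 2e-2)
  }
  # below all truncations the result grows with v^2 (span pinned at b_max)
  r1 <- max_roll_acceleration(2, sta, csts)
  r2 <- max_roll_acceleration(4, sta, csts)
  expect_equal(r2$omega_dot_max / r1$omega_dot_max, 4, tolerance = 1e-6)
  # starling out-rolls the falcon at equal low airspeed; the falcon only
  # approaches the starling's maximum near terminal dive speeds
  expect_gt(max_roll_acceleration(8, sta, csts)$omega_dot_max,
            max_roll_acceleration(8, fal, csts)$omega_dot_max)
  sta_peak <- max(vapply(seq(5, 52, by = 1), function(v)
    max_roll_acceleration(v, sta, csts)$omega_dot_max, numeric(1)))
  expect_lt(max_roll_acceleration(60, fal, csts)$omega_dot_max, sta_peak)
  expect_gt(max_roll_acceleration(120, fal, csts)$omega_dot_max,
            0.5 * sta_peak)
})

test_that("performance envelope is deterministic with definitional columns", {
  grid <- c(5, 10, 20, 40)
  e1 <- performance_envelope(sta, csts, grid)
  e2 <- performance_envelope(sta, csts, grid)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_equal(e1$turn_radius,
               grid^2 / (e1$load_factor * sta$m_total * csts$g /
                           sta$m_total))
  expect_error(performance_envelope(sta, csts, numeric(0)), "empty")
  expect_error(performance_envelope(sta, csts, c(3, 2)), "increasing")
})
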
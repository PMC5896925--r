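test_that("Verlet is exact for constant gravity and force-free motion", {
  m <- 0.5; g <- 9.81; dt <- 1e-3
  w <- c(0, 0, -m * g)
  # Verlet is exact for constant acceleration when a(0) is initialized
  # consistently with the applied force
  st <- bird_state(r = c(0, 0, 100), v = c(12, 0, 0), a = w / m)
  for (i in 1:1000) st <- step_translation(st, w, m, dt)
  t <- 1
  expect_equal(st$r[3], 100 - 0.5 * g * t^2, tolerance = 1e-10)
  expect_equal(st$r[1], 12 * t, tolerance = 1e-10)
  expect_equal(st$v[3], -g * t, tolerance = 1e-10)
  # mechanical energy is conserved exactly under constant gravity
  E0 <- 0.5 * m * 12^2 + m * g * 100
  E1 <- 0.5 * m * sum(st$v^2) + m * g * st$r[3]
  expect_equal(E1, E0, tolerance = 1e-9)
  # zero total force: uniform straight-line motion
  st2 <- bird_state(r = c(0, 0, 0), v = c(3, 4, 0))
  for (i in 1:100) st2 <- step_translation(st2, c(0, 0, 0), m, dt)
  expect_equal(st2$r, c(0.3, 0.4, 0), tolerance = 1e-12)
})

test_that("gravity-plus-drag dive tracks a high-order reference integrator", {
  # vertical fall with quadratic drag; reference from deSolve (lsoda)
  m <- fal$m_total; k <- fal$c_d_body * fal$S_b * 0.5 * csts$rho
  st <- bird_state(r = c(0, 0, 0), v = c(0, 0, -10))
  dt <- 1e-4
  for (i in 1:20000) {
    vz <- st$v[3]
    F <- c(0, 0, -m * csts$g + k * vz^2)
    st <- step_translation(st, F, m, dt)
  }
  ref <- deSolve::lsoda(
    y = c(z = 0, vz = -10), times = c(0, 2),
    func = function(t, y, p) list(c(y["vz"],
                                    -csts$g + k / m * y["vz"]^2)),
    rtol = 1e-12, atol = 1e-12)
  expect_lt(abs(st$r[3] - ref[2, "z"]), 0.01)
  expect_lt(abs(st$v[3] - ref[2, "vz"]), 0.01)
})

test_that("roll step follows the explicit Euler closed form", {
  I <- 1e-3; M <- 2e-3; dt <- 1e-3
  st <- bird_state(r = c(0, 0, 0), v = c(10, 0, 0))
  n <- 500
  for (i in 1:n) st <- step_roll(st, M, I, dt)
  a <- M / I
  expect_equal(st$omega, a * n * dt, tolerance = 1e-12)
  # angle uses the pre-update rate each step: sum a dt^2 (0..n-1)
  expect_equal(st$Omega, a * dt^2 * n * (n - 1) / 2, tolerance = 1e-12)
  # zero torque: angle advances at constant rate
  st2 <- bird_state(r = c(0, 0, 0), v = c(10, 0, 0), omega = 1)
  for (i in 1:100) st2 <- step_roll(st2, 0, I, dt)
  expect_equal(st2$Omega, 0.1, tolerance = 1e-12)
  expect_error(step_roll(st, M, -1, dt), "positive")
})

test_that("body axes stay orthonormal and right-handed through rolling flight", {
  set.seed(42)
  st <- bird_state(r = c(0, 0, 0), v = c(8, 3, -2), Omega = 0.3)
  for (i in 1:500) {
    F <- stats::rnorm(3, sd = 2)
    st <- step_translation(st, F, 0.5, 1e-3)
    st <- step_roll(st, stats::rnorm(1, sd = 1e-3), 1e-3, 1e-3)
    ax <- st$axes
    G <- rbind(ax$ex, ax$ey, ax$ez)
    expect_lt(max(abs(G %*% t(G) - diag(3))), 1e-12)
    expect_equal(vcross_test(ax$ex, ax$ey), ax$ez, tolerance = 1e-12)
    expect_equal(ax$ex, st$v / sqrt(sum(st$v^2)), tolerance = 1e-12)
  }
})

test_that("speed converges to a bounded equilibrium under drag", {
  # thrust-free fall with drag approaches terminal speed (the approach is
  # asymptotic with a ~5 s time constant, so start near the equilibrium)
  m <- sta$m_total; k <- sta$c_d_body * sta$S_b * 0.5 * csts$rho
  st <- bird_state(r = c(0, 0, 0), v = c(0, 0, -45))
  for (i in 1:200000) {
    vz <- st$v[3]
    st <- step_translation(st, c(0, 0, -m * csts$g + k * vz^2), m, 1e-4)
  }
  v_term <- sqrt(m * csts$g / k)
  expect_lt(abs(abs(st$v[3]) - v_term) / v_term, 2e-4)
})
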
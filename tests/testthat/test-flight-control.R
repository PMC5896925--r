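test_that("weight support compensates gravity and discards forward demand", {
  ax <- body_axes(c(10, 0, 0), Omega = 0)
  # zero command, wings level: demand is exactly weight support
  ws <- weight_support(c(0, 0, 0), ax, g = 9.81)
  expect_equal(ws$magnitude, 9.81)
  expect_equal(ws$a_proj, c(0, 0, 9.81))
  # components along the roll axis are discarded
  ws2 <- weight_support(c(5, 0, 0), ax, g = 9.81)
  expect_equal(ws2$magnitude, 9.81)
  # 3g horizontal demand plus weight support: |a_proj| = g sqrt(10)
  ws3 <- weight_support(c(0, 3 * 9.81, 0), ax, g = 9.81)
  expect_equal(ws3$magnitude, 9.81 * sqrt(10), tolerance = 1e-12)
  # strict (uncompensated) sign mode kept for comparison
  ws4 <- weight_support(c(0, 0, 0), ax, g = 9.81, strict_sign = TRUE)
  expect_equal(ws4$a_proj, c(0, 0, -9.81))
})

test_that("roll target aligns the lift axis with the demand", {
  ax <- body_axes(c(10, 0, 0), Omega = 0.4)
  set.seed(5)
  for (i in 1:20) {
    demand <- stats::rnorm(3)
    ay <- sum(demand * ax$ey); az <- sum(demand * ax$ez)
    g0 <- roll_target(list(ay = ay, az = az,
                           magnitude = sqrt(ay^2 + az^2)))
    # rolling by the returned angle must align e_z' with the demand
    ax2 <- body_axes(c(10, 0, 0), Omega = 0.4 + g0)
    dproj <- demand - sum(demand * ax$ex) * ax$ex
    cosang <- sum(dproj * ax2$ez) / sqrt(sum(dproj^2))
    expect_equal(cosang, 1, tolerance = 1e-9)
  }
  # demand along e_z': no roll; along e_y': a quarter turn
  expect_equal(roll_target(list(ay = 0, az = 2, magnitude = 2)), 0)
  expect_equal(abs(roll_target(list(ay = 1.5, az = 0, magnitude = 1.5))),
               pi / 2)
  # sign flips with the demand side
  gp <- roll_target(list(ay = 1, az = 1, magnitude = sqrt(2)))
  gm <- roll_target(list(ay = -1, az = 1, magnitude = sqrt(2)))
  expect_equal(gp, -gm)
  expect_equal(roll_target(list(ay = 0, az = 0, magnitude = 0)), 0)
})

test_that("bang-bang switching rule and minimum-time closed form agree", {
  # direct rule checks
  expect_equal(bang_bang_roll(gamma = 1, omega = -2, max_accel = 10), 1)
  expect_equal(bang_bang_roll(gamma = -1, omega = 2, max_accel = 10), -1)
  # same-signed rate past the switching curve: brake
  expect_equal(bang_bang_roll(gamma = 0.1, omega = 2, max_accel = 10), -1)
  expect_equal(bang_bang_roll(gamma = 0.1, omega = 1, max_accel = 10), 1)
  expect_error(bang_bang_roll(1, 0, -5), "positive")

  # discrete simulation from rest: switch at half the angle, arrival at
  # the closed-form minimum time 2 sqrt(gamma / a)
  a <- 5000; target <- pi; dt <- 1e-5
  om <- 0; gam <- target; t <- 0; switched_at <- NA
  while (gam > 1e-4 || abs(om) > 0.05) {
    s <- bang_bang_roll(gam, om, a)
    if (is.na(switched_at) && s < 0) switched_at <- target - gam
    gam <- gam - om * dt
    om <- om + s * a * dt
    t <- t + dt
    if (t > 1) break
  }
  expect_equal(switched_at, target / 2, tolerance = 0.01)
  expect_equal(t, 2 * sqrt(target / a), tolerance = 0.01)
})

test_that("bang-bang roll maneuvers converge across step sizes", {
  # pi-radian roll at 5000 rad/s^2: the dt = 1e-4 trajectory deviates from
  # the dt = 1e-5 reference by well under 0.01 rad at matched times
  sim <- function(dt, t_end) {
    n <- round(t_end / dt)
    om <- 0; gam <- pi; out <- numeric(n)
    for (i in 1:n) {
      s <- bang_bang_roll(gam, om, 5000)
      gam <- gam - om * dt
      om <- om + s * 5000 * dt
      out[i] <- gam
    }
    out
  }
  t_end <- 0.06
  coarse <- sim(1e-4, t_end)
  fine <- sim(1e-5, t_end)[seq(10, round(t_end / 1e-5), by = 10)]
  expect_lt(max(abs(coarse - fine)), 0.01)
})
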
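test_that("initial geometry follows the configuration", {
  cfg <- engagement_config(altitude = 300, horiz_dist = 400,
                           prey_mode = "straight", timeout = 0.05,
                           dt = 1e-3, log_dt = 1e-3)
  r <- run_engagement(cfg, seed = 1)
  tr <- r$trajectory
  expect_equal(tr$distance[1], 500)        # 3-4-5 triangle
  expect_equal(c(tr$falcon_x[1], tr$falcon_y[1], tr$falcon_z[1]),
               c(400, 0, 300))
  expect_equal(c(tr$prey_x[1], tr$prey_y[1], tr$prey_z[1]), c(0, 0, 0))
  expect_equal(tr$falcon_speed[1], 16)
  expect_equal(tr$prey_speed[1], 11)
  # falcon velocity points straight at the prey at t = 0
  dr <- c(tr$falcon_x[2] - tr$falcon_x[1], tr$falcon_y[2] - tr$falcon_y[1],
          tr$falcon_z[2] - tr$falcon_z[1])
  expect_lt(acos(sum(-dr * c(400, 0, 300)) /
                   (sqrt(sum(dr^2)) * 500)), 0.02)
})

test_that("degenerate zero-range start is an immediate catch", {
  cfg <- engagement_config(altitude = 0.05, horiz_dist = 0.05)
  r <- run_engagement(cfg, seed = 1)
  expect_identical(r$outcome, "catch")
  expect_identical(r$t_end, 0)
})

test_that("engagements are bit-reproducible for identical seed and config", {
  cfg <- engagement_config(N = 3, altitude = 150, horiz_dist = 80,
                           prey_mode = "nonsmooth", dt = 1e-3)
  a <- run_engagement(cfg, seed = 123)
  b <- run_engagement(cfg, seed = 123)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$trajectory, b$trajectory)
  c2 <- run_engagement(cfg, seed = 124)
  expect_false(identical(a$min_distance, c2$min_distance))
})

test_that("exact fast vision on straight prey yields a catch", {
  cfg <- engagement_config(N = 3, altitude = 120, horiz_dist = 90,
                           tau = 1e-4, xi = 0, prey_mode = "straight")
  r <- run_engagement(cfg, seed = 2)
  expect_identical(r$outcome, "catch")
  expect_lte(r$min_distance, 0.2)
  expect_gt(r$intercept_speed, r$config$v0_falcon)
})

test_that("unreachable prey times out at the configured horizon", {
  cfg <- engagement_config(N = 0.01, altitude = -50, horiz_dist = 1500,
                           prey_mode = "straight", dt = 1e-3, timeout = 5)
  r <- run_engagement(cfg, seed = 3)
  expect_identical(r$outcome, "timeout")
  expect_identical(r$t_end, 5)
})

test_that("outcomes are mutually exclusive, exhaustive, and tunnel-free", {
  cfg <- engagement_config(prey_mode = "nonsmooth", dt = 1e-3,
                           timeout = 20)
  outs <- vapply(1:25, function(s) {
    set.seed(s)
    cfg$altitude <- stats::runif(1, -100, 800)
    cfg$horiz_dist <- stats::runif(1, 0, 500)
    cfg$N <- stats::runif(1, 1, 15)
    run_engagement(cfg, seed = s)$outcome
  }, character(1))
  expect_true(all(outs %in% c("catch", "near_miss", "timeout")))
  expect_gt(length(unique(outs)), 1)
  # no tunneling: worst-case closing displacement per step stays under the
  # catch radius at the default step size
  v_close_max <- 130 + 25
  expect_lt(v_close_max * engagement_config()$dt, 0.2)
})

test_that("prey initial headings are uniform over azimuth", {
  cfg <- engagement_config(prey_mode = "straight", timeout = 0.02,
                           dt = 1e-2, log_dt = 1e-2)
  az <- vapply(1:300, function(s) {
    tr <- run_engagement(cfg, seed = s)$trajectory
    atan2(tr$prey_y[2] - tr$prey_y[1], tr$prey_x[2] - tr$prey_x[1])
  }, numeric(1))
  R <- sqrt(mean(cos(az))^2 + mean(sin(az))^2)
  expect_lt(R, 4 / sqrt(length(az)) + 0.08)
  ks <- stats::ks.test((az + pi) / (2 * pi), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("stoop from high altitude reaches stoop-like intercept speeds", {
  cfg <- engagement_config(N = 2.8, altitude = 1500, horiz_dist = 641,
                           prey_mode = "nonsmooth", dt = 1e-3)
  r <- run_engagement(cfg, seed = 7)
  expect_gt(max(r$trajectory$falcon_speed), 80)
  expect_lt(max(r$trajectory$falcon_speed), 130)  # bounded by terminal speed
})
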
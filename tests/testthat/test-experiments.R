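test_that("strategy sweeps are reproducible and respect sampling bounds", {
  cfg <- engagement_config(prey_mode = "nonsmooth", dt = 1e-3,
                           timeout = 10)
  a <- sweep_strategies(10, cfg, seed = 5)
  b <- sweep_strategies(10, cfg, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$N >= 1 & a$N <= 20))
  expect_true(all(a$altitude >= -200 & a$altitude <= 1500))
  expect_true(all(a$horiz_dist >= 0 & a$horiz_dist <= 800))
  expect_setequal(unique(a$outcome),
                  intersect(unique(a$outcome),
                            c("catch", "near_miss", "timeout")))
})

test_that("strategy draws are uniform over each coordinate", {
  cfg <- engagement_config(prey_mode = "straight", dt = 1e-2,
                           timeout = 0.02)
  sw <- sweep_strategies(600, cfg, seed = 8)
  expect_gt(stats::ks.test((sw$N - 1) / 19, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test((sw$altitude + 200) / 1700, "punif")$p.value,
            0.01)
  expect_gt(stats::ks.test(sw$horiz_dist / 800, "punif")$p.value, 0.01)
})

test_that("surface fit recovers a known logistic optimum", {
  set.seed(21)
  n <- 4000
  d <- tibble::tibble(
    N = stats::runif(n, 1, 20),
    altitude = stats::runif(n, -200, 1500),
    horiz_dist = stats::runif(n, 0, 800))
  eta <- 2 - ((d$N - 6) / 4)^2 - ((d$altitude - 900) / 500)^2 -
    ((d$horiz_dist - 300) / 300)^2
  d$caught <- stats::runif(n) < stats::plogis(eta)
  surf <- fit_catch_surface(d)
  opt <- locate_optimum(surf, n_grid = 50)
  expect_lt(abs(opt$N - 6), 1.5)
  expect_lt(abs(opt$altitude - 900), 150)
  expect_lt(abs(opt$horiz_dist - 300), 100)
  expect_true(all(opt$p_catch >= 0 & opt$p_catch <= 1))
  g <- glance(surf)
  expect_equal(g$nobs, n)
  td <- tidy(surf)
  expect_setequal(td$term, c("s(N)", "s(altitude)", "s(horiz_dist)"))
})

test_that("degenerate outcomes produce a flat flagged surface", {
  d <- tibble::tibble(N = 1:20, altitude = 1:20, horiz_dist = 1:20,
                      caught = TRUE)
  surf <- fit_catch_surface(d)
  expect_true(surf$degenerate)
  expect_null(locate_optimum(surf))
  expect_true(glance(surf)$degenerate)
})

test_that("inactive performance caps reproduce the baseline engagement", {
  cfg <- engagement_config(N = 2.8, altitude = 400, horiz_dist = 200,
                           prey_mode = "nonsmooth", dt = 1e-3)
  base <- run_engagement(cfg, seed = 44)
  same <- run_engagement(cfg, seed = 44, cap_load = Inf,
                         cap_roll_accel = Inf)
  expect_identical(tidy(base), tidy(same))
  # an aggressive cap changes the engagement
  capped <- run_engagement(cfg, seed = 44, cap_load = 0.5 * fal$L0,
                           cap_roll_accel = 50)
  expect_false(identical(base$min_distance, capped$min_distance))
})

test_that("convergence discrepancies shrink about an order per dt decade", {
  rep <- convergence_report(dts = c(1e-2, 1e-3), seed = 6)
  expect_setequal(unique(rep$quantity),
                  c("distance", "falcon_speed", "falcon_accel",
                    "prey_speed", "prey_accel"))
  wide <- tidyr::pivot_wider(rep, id_cols = "quantity",
                             names_from = "dt",
                             values_from = "discrepancy")
  ratio <- wide[["0.01"]] / wide[["0.001"]]
  # speeds and distances contract strongly; acceleration discrepancies are
  # dominated by the discontinuous prey/roll commands and contract less
  expect_true(all(ratio > 1))
  expect_gt(median(ratio), 3)
})

test_that("robustness sweep reports an optimum per parameter value", {
  cfg <- engagement_config(prey_mode = "straight", dt = 1e-3, timeout = 8)
  rb <- robustness_sweep("tau", values = c(0.01, 0.1), n_samples = 40,
                         config = cfg, seed = 2)
  expect_equal(nrow(rb), 2)
  expect_true(all(rb$catch_fraction >= 0 & rb$catch_fraction <= 1))
  expect_true(all(is.finite(rb$opt_p) | is.na(rb$opt_p)))
})
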
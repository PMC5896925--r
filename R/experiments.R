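#' Monte-Carlo sweep over attack strategies
#'
#' Draws attack strategies uniformly at random — navigation constant `N`
#' in `[1, 20]`, initial altitude in `[-200, 1500]` m, horizontal distance
#' in `[0, 800]` m — and runs one engagement per draw. Each engagement
#' gets its own seed derived from `seed`, so any row can be replayed with
#' [run_engagement()].
#'
#' @param n_samples Number of strategies to draw.
#' @param config Template [engagement_config()]; `N`, `altitude` and
#'   `horiz_dist` are overwritten per draw, everything else (prey mode,
#'   delays, errors, `dt`) is shared.
#' @param falcon,prey,consts As in [run_engagement()].
#' @param seed Root seed for the sweep.
#' @param N_range,altitude_range,horiz_range Sampling bounds.
#' @return A tibble with one row per engagement: the drawn strategy, the
#'   per-engagement seed, `outcome`, `caught` (logical), `t_end`,
#'   `intercept_speed`, `min_distance`.
#' @export
sweep_strategies <- function(n_samples, config = engagement_config(),
                             falcon = falcon_morphology(),
                             prey = starling_morphology(),
                             consts = flight_constants(), seed = 1,
                             N_range = c(1, 20),
                             altitude_range = c(-200, 1500),
                             horiz_range = c(0, 800)) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  draws <- tibble::tibble(
    N = stats::runif(n_samples, N_range[1], N_range[2]),
    altitude = stats::runif(n_samples, altitude_range[1], altitude_range[2]),
    horiz_dist = stats::runif(n_samples, horiz_range[1], horiz_range[2]),
    engagement_seed = sample.int(.Machine$integer.max - 1, n_samples))
  res <- purrr::pmap(draws, function(N, altitude, horiz_dist,
                                     engagement_seed) {
    cfg <- config
    cfg$N <- N; cfg$altitude <- altitude; cfg$horiz_dist <- horiz_dist
    r <- run_engagement(cfg, falcon, prey, consts, seed = engagement_seed)
    tibble::tibble(outcome = r$outcome, t_end = r$t_end,
                   intercept_speed = r$intercept_speed,
                   min_distance = r$min_distance)
  })
  out <- dplyr::bind_cols(draws, dplyr::bind_rows(res))
  out$caught <- out$outcome == "catch"
  attr(out, "prey_mode") <- config$prey$mode
  out
}

#' Fit a catch-success response surface
#'
#' Logistic generalized additive model of catch probability over the three
#' strategy coordinates, `caught ~ s(N) + s(altitude) + s(horiz_dist)`,
#' with penalized-likelihood smoothness selection and no cap on the
#' effective degrees of freedom. The fitted surface interpolates between
#' the sampled strategies; optima are read off a dense evaluation grid.
#'
#' @param samples Output of [sweep_strategies()] (needs columns `N`,
#'   `altitude`, `horiz_dist`, `caught`).
#' @param k Basis dimension per smooth (passed to `mgcv::s`).
#' @return An object of class `catch_surface` wrapping the `mgcv::gam`
#'   fit. Degenerate inputs (all caught or none caught) yield a flat
#'   surface flagged `degenerate`.
#' @export
fit_catch_surface <- function(samples, k = 10) {
  stopifnot(all(c("N", "altitude", "horiz_dist", "caught") %in%
                  names(samples)))
  degenerate <- length(unique(samples$caught)) < 2
  fit <- if (degenerate) NULL else
    mgcv::gam(caught ~ s(N, k = k) + s(altitude, k = k) +
                s(horiz_dist, k = k),
              family = stats::binomial(), data = samples)
  structure(list(fit = fit, samples = samples, degenerate = degenerate,
                 p_flat = mean(samples$caught)),
            class = "catch_surface")
}

#' Locate the optimum of a fitted catch surface
#'
#' Evaluates the fitted probability on a regular grid over the sampled
#' ranges and returns the maximizing strategy.
#'
#' @param surface A [fit_catch_surface()] object.
#' @param n_grid Grid points per dimension.
#' @return A one-row tibble: `N`, `altitude`, `horiz_dist`, `p_catch`;
#'   `NULL` for a degenerate surface.
#' @export
locate_optimum <- function(surface, n_grid = 50) {
  stopifnot(inherits(surface, "catch_surface"))
  if (surface$degenerate) return(NULL)
  s <- surface$samples
  grid <- tidyr::expand_grid(
    N = seq(min(s$N), max(s$N), length.out = n_grid),
    altitude = seq(min(s$altitude), max(s$altitude), length.out = n_grid),
    horiz_dist = seq(min(s$horiz_dist), max(s$horiz_dist),
                     length.out = n_grid))
  grid$p_catch <- as.numeric(
    mgcv::predict.gam(surface$fit, newdata = grid, type = "response"))
  grid[which.max(grid$p_catch), ]
}

#' @export
print.catch_surface <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<catch_surface> degenerate (all outcomes identical, p = %.2f)\n",
                x$p_flat))
  } else {
    opt <- locate_optimum(x)
    cat(sprintf("<catch_surface> n = %d, optimum p = %.2f at N = %.1f, altitude = %.0f m, distance = %.0f m\n",
                nrow(x$samples), opt$p_catch, opt$N, opt$altitude,
                opt$horiz_dist))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.catch_surface <- function(x, ...) {
  if (x$degenerate)
    return(tibble::tibble(term = character(), edf = numeric(),
                          ref_df = numeric(), statistic = numeric(),
                          p.value = numeric()))
  s <- summary(x$fit)
  tibble::tibble(term = rownames(s$s.table),
                 edf = s$s.table[, "edf"],
                 ref_df = s$s.table[, "Ref.df"],
                 statistic = s$s.table[, "Chi.sq"],
                 p.value = s$s.table[, "p-value"])
}

#' @importFrom generics glance
#' @export
glance.catch_surface <- function(x, ...) {
  n <- nrow(x$samples)
  p <- mean(x$samples$caught)
  ci <- stats::binom.test(sum(x$samples$caught), n)$conf.int
  base <- tibble::tibble(nobs = n, p_catch = p,
                         p_catch_low = ci[1], p_catch_high = ci[2],
                         degenerate = x$degenerate)
  if (x$degenerate) return(base)
  base$deviance <- stats::deviance(x$fit)
  base$aic <- stats::AIC(x$fit)
  base
}

#' Plot a catch-success surface
#'
#' Fitted catch probability over altitude and horizontal distance, at a
#' set of navigation-constant slices.
#'
#' @param object A `catch_surface`.
#' @param N_slices Values of `N` at which to slice the surface.
#' @param n_grid Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.catch_surface <- function(object, N_slices = c(1, 2.8, 5.6, 15),
                                   n_grid = 40, ...) {
  if (object$degenerate) stop("degenerate surface: nothing to plot",
                              call. = FALSE)
  s <- object$samples
  grid <- tidyr::expand_grid(
    N = N_slices,
    altitude = seq(min(s$altitude), max(s$altitude), length.out = n_grid),
    horiz_dist = seq(min(s$horiz_dist), max(s$horiz_dist),
                     length.out = n_grid))
  grid$p_catch <- as.numeric(
    mgcv::predict.gam(object$fit, newdata = grid, type = "response"))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$horiz_dist,
                                     y = .data$altitude,
                                     fill = .data$p_catch)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~N, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "horizontal distance (m)", y = "initial altitude (m)",
                  fill = "P(catch)")
}

#' Robustness sweep over a guidance-loop parameter
#'
#' Repeats the strategy sweep and surface fit for each value of one
#' parameter of the falcon's sensing/control chain (`tau`, `xi` or `chi`)
#' and reports how the fitted optimum drifts.
#'
#' @param parameter `"tau"`, `"xi"` or `"chi"`.
#' @param values Parameter values to test.
#' @param n_samples Engagements per value.
#' @param config Base [engagement_config()].
#' @inheritParams sweep_strategies
#' @return A tibble with one row per value: the parameter value, the
#'   fitted optimum (`N`, `altitude`, `horiz_dist`, `p_catch`), and the
#'   raw catch fraction.
#' @export
robustness_sweep <- function(parameter = c("tau", "xi", "chi"), values,
                             n_samples = 500,
                             config = engagement_config(),
                             falcon = falcon_morphology(),
                             prey = starling_morphology(),
                             consts = flight_constants(), seed = 1) {
  parameter <- match.arg(parameter)
  stopifnot(all(is.finite(values)))
  rows <- purrr::imap(values, function(val, i) {
    cfg <- config
    cfg[[parameter]] <- val
    sw <- sweep_strategies(n_samples, cfg, falcon, prey, consts,
                           seed = seed + i)
    surf <- fit_catch_surface(sw)
    opt <- locate_optimum(surf)
    tibble::tibble(parameter = parameter, value = val,
                   catch_fraction = mean(sw$caught),
                   opt_N = if (is.null(opt)) NA_real_ else opt$N,
                   opt_altitude = if (is.null(opt)) NA_real_ else opt$altitude,
                   opt_horiz = if (is.null(opt)) NA_real_ else opt$horiz_dist,
                   opt_p = if (is.null(opt)) mean(sw$caught) else opt$p_catch)
  })
  dplyr::bind_rows(rows)
}

#' Capped-performance experiment
#'
#' Tests which component of high-speed flight performance drives catch
#' success: engagements are run with the falcon's maximum lift and/or roll
#' acceleration artificially capped at the values attainable in sustained
#' level flight (a reference speed of 30 m s^-1 by default), for a
#' steep high-altitude stoop and for a level attack entered at very high
#' initial speed (112 m s^-1).
#'
#' @param n_per_condition Engagements per condition.
#' @param config Base config; the stoop condition uses its
#'   altitude/distance, the level condition sets `altitude = 0` and
#'   `v0_falcon = 112`.
#' @param cap_speed Reference airspeed whose attainable lift / roll
#'   acceleration define the caps (m s^-1).
#' @inheritParams sweep_strategies
#' @return A tibble with one row per condition x cap combination:
#'   `condition`, `cap`, `catch_fraction`, binomial CI bounds.
#' @export
capped_performance_experiment <- function(n_per_condition = 200,
                                          config = engagement_config(
                                            N = 2.8, altitude = 1500,
                                            horiz_dist = 641),
                                          cap_speed = 30,
                                          falcon = falcon_morphology(),
                                          prey = starling_morphology(),
                                          consts = flight_constants(),
                                          seed = 1) {
  L_cap <- max(max_lift_flapping(cap_speed, falcon, consts),
               max_lift_gliding(cap_speed, falcon, consts)$L_max)
  roll_cap <- max_roll_acceleration(cap_speed, falcon, consts)$omega_dot_max
  caps <- list(none = c(Inf, Inf), load = c(L_cap, Inf),
               roll = c(Inf, roll_cap), both = c(L_cap, roll_cap))
  conditions <- list(
    stoop = config,
    level_fast = {
      cfg <- config; cfg$altitude <- 0; cfg$v0_falcon <- 112; cfg
    })
  rows <- purrr::imap(conditions, function(cfg, cond) {
    purrr::imap(caps, function(cap, cap_name) {
      set.seed(seed + 1000 * match(cond, names(conditions)) +
                 match(cap_name, names(caps)))
      seeds <- sample.int(.Machine$integer.max - 1, n_per_condition)
      caught <- purrr::map_lgl(seeds, function(s)
        run_engagement(cfg, falcon, prey, consts, seed = s,
                       cap_load = cap[1],
                       cap_roll_accel = cap[2])$outcome == "catch")
      ci <- stats::binom.test(sum(caught), n_per_condition)$conf.int
      tibble::tibble(condition = cond, cap = cap_name,
                     n = n_per_condition,
                     catch_fraction = mean(caught),
                     ci_low = ci[1], ci_high = ci[2])
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Numerical convergence report
#'
#' Measures the discrepancy between trajectories integrated at a time step
#' `dt` and at `dt / 10`, with identical random seeding:
#' `e_dt = (1/k) sum_n || f_{dt/10}(10 n) - f_dt(n) ||`
#' over the k coarse steps both runs share before first interception.
#' Reported per quantity: predator-prey distance, predator speed and
#' acceleration, prey speed and acceleration. Smooth-maneuvering prey is
#' the default scenario because its forcing draws no per-step random
#' numbers, keeping the two runs seed-comparable.
#'
#' @param dts Coarse step sizes to test (each compared against a tenth of
#'   itself).
#' @param config Engagement scenario (the stoop from 800 m altitude and
#'   600 m horizontal distance by default).
#' @inheritParams sweep_strategies
#' @return A tibble: `dt`, `quantity`, `discrepancy`, `k`.
#' @export
convergence_report <- function(dts = c(1e-2, 1e-3),
                               config = engagement_config(
                                 altitude = 800, horiz_dist = 600,
                                 prey_mode = "smooth"),
                               falcon = falcon_morphology(),
                               prey = starling_morphology(),
                               consts = flight_constants(), seed = 1) {
  run_at <- function(dt) {
    cfg <- config
    cfg$dt <- dt
    cfg$log_dt <- dt   # log every step
    run_engagement(cfg, falcon, prey, consts, seed = seed)
  }
  quantities <- c(distance = "distance", falcon_speed = "falcon_speed",
                  falcon_accel = "falcon_accel", prey_speed = "prey_speed",
                  prey_accel = "prey_accel")
  rows <- purrr::map(dts, function(dt) {
    coarse <- run_at(dt)
    fine <- run_at(dt / 10)
    tc <- coarse$trajectory
    tf <- fine$trajectory[seq(1, nrow(fine$trajectory), by = 10), ]
    k <- min(nrow(tc), nrow(tf))
    purrr::imap(quantities, function(col, nm) {
      tibble::tibble(dt = dt, quantity = nm,
                     discrepancy = mean(abs(tc[[col]][seq_len(k)] -
                                              tf[[col]][seq_len(k)])),
                     k = k)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
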
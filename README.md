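# stoopsim

Physics-based simulation of aerial attacks by peregrine falcons
(*Falco peregrinus*) on starling-like prey, built to ask a behavioral
question with mechanics: **when and why does the high-speed stoop — the
falcon's signature dive from altitude — maximize catch success?**

The package is an agent-based 3-D flight simulator for two interacting
birds:

* **Flight mechanics** — a quasi-steady, wingbeat-averaged force law for
  flapping and gliding flight. Net thrust while flapping is
  `(1 − c_l²/c_l,max²)·(π³/16)·ρ b² sin²(θ/2) f² l_w² · c_torque`, less
  parasite and lifting-line induced drag; muscle torque caps lift at
  `L0 = 1.7 m g` at full span and cuts thrust above a threshold speed
  (`c_torque = min(1, v_thresh/v)`). Gliding birds retract their wings
  to the drag-optimal span `b* ∝ (L*²)^{1/3}` for the demanded lift.
  Translation integrates by velocity Verlet; banking follows a
  minimum-time (bang-bang) roll law with torque from antisymmetric lift
  and a retraction-dependent roll inertia.
* **Guidance** — the falcon uses pure proportional navigation,
  `a* = N λ̇ × v`, on a line-of-sight rate estimated from noisy visual
  measurements sampled and held every τ (50 ms by default, angular
  error up to ξ = 0.14·τ rad). The prey flies one of three open-loop
  programs: straight, smoothly turning, or erratic jinking with ~80
  direction switches per second.
* **Experiments** — Monte-Carlo sweeps over attack strategies
  (navigation constant, initial altitude and horizontal distance),
  logistic GAM response surfaces of catch probability (mgcv),
  robustness sweeps over delay and error parameters,
  performance-capping experiments, and numerical convergence reports.

Intended users: behavioral ecologists and biomechanists studying
pursuit–evasion, and guidance-and-control people who want a biological
testbed with honest flight physics.

## Worked example

Flight performance landmarks of the model falcon:

```r
library(stoopsim)
envelope_speeds(falcon_morphology())
#> # A tibble: 3 × 2
#>   quantity             speed
#>   <chr>                <dbl>
#> 1 max_level_speed      28.6
#> 2 terminal_dive_speed 126.
#> 3 min_sustained_speed   8.61
```

Maximum sustained level speed is the airspeed where maximum level
thrust-minus-drag crosses zero with lift pinned to weight (28.6 m/s;
starlings give 23.9); terminal dive speed is where drag balances weight
with wings fully tucked (126 m/s; starlings 49.6).

A single stoop from 1500 m altitude and 641 m horizontal distance at
the navigation constant `N = 2.8` against jinking prey:

```r
r <- run_engagement(engagement_config(N = 2.8, altitude = 1500,
                                      horiz_dist = 641,
                                      prey_mode = "nonsmooth"), seed = 2)
r
#> <engagement_result> catch at t = 21.486 s (min distance 0.200 m, intercept speed 103.5 m/s)
```

The falcon converts 1.5 km of altitude into an interception at
103.5 m/s — a catch is scored when it passes within 0.2 m of the prey.
`r$trajectory` holds the decimated flight paths (`autoplot(r)` draws
them); `tidy(r)` gives a one-row summary. Batch experiments chain the
same way:

```r
sw <- sweep_strategies(2000, engagement_config(prey_mode = "nonsmooth",
                                               dt = 1e-3), seed = 42)
surf <- fit_catch_surface(sw)
locate_optimum(surf)    # best strategy on the fitted surface
glance(surf)            # catch fraction with binomial CI
```

A thin CLI (`inst/exec/stoopsim`) exposes `run-engagement`, `sweep`,
`envelope` and `convergence` subcommands over the same functions.

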